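#' Sparse participant-feature specification
#'
#' Defines the one-hot layout of the wide branch's categorical participant
#' features: a subject-id block (size S), a sex block (size 2) and an
#' age-group block (size A), concatenated to a length `T = S + 2 + A` 0/1
#' vector.
#'
#' @param subject_ids Subject-id vocabulary (training subjects).
#' @param sexes Sex vocabulary.
#' @param age_groups Age-bin vocabulary.
#' @return A `sparse_feature_spec` with the block layout and total length
#'   `total` (T).
#' @export
sparse_feature_spec <- function(subject_ids, sexes = c("M", "F"),
                                age_groups = c("young", "mid", "old")) {
  subject_ids <- as.character(subject_ids)
  blocks <- list(subject = subject_ids, sex = sexes, age_group = age_groups)
  sizes <- vapply(blocks, length, 0L)
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  names(starts) <- names(blocks)
  structure(list(blocks = blocks, sizes = sizes, starts = starts,
                 total = sum(sizes)),
            class = "sparse_feature_spec")
}

#' One-hot encode a participant
#'
#' Encodes a [subject_profile()] under a [sparse_feature_spec()]: exactly one
#' 1 per field block. A subject id outside the vocabulary yields an all-zero
#' subject block (the unknown-subject convention used for held-out
#' participants), while unknown sex or age group is an error.
#'
#' @param profile A [subject_profile()].
#' @param spec A [sparse_feature_spec()].
#' @return Numeric 0/1 vector of length `spec$total`.
#' @export
one_hot_encode <- function(profile, spec) {
  d2 <- numeric(spec$total)
  si <- match(profile$subject_id, spec$blocks$subject)
  if (!is.na(si)) d2[spec$starts["subject"] + si] <- 1
  sx <- match(profile$sex, spec$blocks$sex)
  if (is.na(sx)) stopf("unknown sex '%s'", profile$sex)
  d2[spec$starts["sex"] + sx] <- 1
  ag <- match(profile$age_group, spec$blocks$age_group)
  if (is.na(ag)) stopf("unknown age_group '%s'", profile$age_group)
  d2[spec$starts["age_group"] + ag] <- 1
  d2
}

#' Cross-product feature specification
#'
#' A boolean matrix with one row per cross feature and one column per one-hot
#' position; each cross is the product (logical AND, for 0/1 inputs) of the
#' selected positions. Rows with fewer than two selected positions are
#' rejected -- an empty or singleton product is not a cross.
#'
#' @param mat Logical matrix, k x T.
#' @param spec The [sparse_feature_spec()] the columns refer to.
#' @return A `cross_spec`.
#' @export
cross_spec <- function(mat, spec) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "logical"
  if (ncol(mat) != spec$total) {
    stopf("cross matrix has %d columns but the feature length is %d",
          ncol(mat), spec$total)
  }
  if (nrow(mat) > 0 && any(rowSums(mat) < 2)) {
    stopf("every cross must select at least 2 features")
  }
  structure(list(mat = mat, k = nrow(mat)), class = "cross_spec")
}

#' Default crosses: all pairwise combinations across field blocks
#'
#' Builds one cross for every pair of levels drawn from two distinct field
#' blocks (subject x sex, subject x age, sex x age) -- the minimal cross set
#' that lets the wide branch memorize demographic- and subject-specific
#' response patterns.
#'
#' @param spec A [sparse_feature_spec()].
#' @return A [cross_spec()].
#' @export
default_cross_spec <- function(spec) {
  bn <- names(spec$blocks)
  rows <- list()
  rn <- character(0)
  for (a in seq_along(bn)) {
    for (b in seq_along(bn)) {
      if (b <= a) next
      for (i in seq_len(spec$sizes[a])) {
        for (j in seq_len(spec$sizes[b])) {
          r <- logical(spec$total)
          r[spec$starts[a] + i] <- TRUE
          r[spec$starts[b] + j] <- TRUE
          rows[[length(rows) + 1L]] <- r
          rn <- c(rn, paste0(bn[a], "=", spec$blocks[[a]][i], ":",
                             bn[b], "=", spec$blocks[[b]][j]))
        }
      }
    }
  }
  m <- if (length(rows) > 0) do.call(rbind, rows) else matrix(FALSE, 0, spec$total)
  rownames(m) <- rn
  cross_spec(m, spec)
}

#' Evaluate cross-product features
#'
#' For each cross `k`, the product of the selected entries of `d2`; on 0/1
#' inputs this is the AND of the selected indicators.
#'
#' @param d2 Numeric vector of length T.
#' @param cross A [cross_spec()].
#' @return Numeric vector of length `cross$k`.
#' @export
cross_products <- function(d2, cross) {
  if (length(d2) != ncol(cross$mat)) {
    stopf("d2 has length %d but the cross spec expects %d", length(d2),
          ncol(cross$mat))
  }
  apply(cross$mat, 1, function(sel) prod(d2[sel]))
}

#' Assemble the wide-branch input vector
#'
#' Concatenates the flattened epoch (row-major: channel 1's 90 samples, then
#' channel 2's, ...), the one-hot participant vector and its cross products
#' into the wide input `x` of length `d1 + T + k` (2700 + T + k for the
#' 30 x 90 epoch).
#'
#' @param epoch Numeric matrix, channels x samples (30 x 90).
#' @param d2 One-hot vector from [one_hot_encode()].
#' @param dphi Cross products from [cross_products()].
#' @return Numeric vector of length `prod(dim(epoch)) + length(d2) +
#'   length(dphi)`.
#' @export
assemble_wide_input <- function(epoch, d2, dphi) {
  if (length(dim(epoch)) != 2) stopf("epoch must be a channels x samples matrix")
  unname(c(as.numeric(t(epoch)), d2, dphi))
}
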