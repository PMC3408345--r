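#' Estimate the background expression threshold from a sex-marker gene
#'
#' Uses a gene expressed in one sex only (e.g. XIST, silent in males): the
#' background level is the median log2 intensity of the marker across all
#' samples of the non-expressing sex.
#'
#' @param study An [expression_study].
#' @param marker_gene Gene id of the sex marker.
#' @param negative_sex `"M"` or `"F"`: the sex in which the marker is silent.
#' @return The median log2 intensity (a single number).
#' @export
estimate_background_threshold <- function(study, marker_gene,
                                          negative_sex = "M") {
  if (!marker_gene %in% rownames(study$matrix))
    stop("marker gene '", marker_gene, "' not present in the study")
  neg <- study$samples$sample_id[study$samples$sex == negative_sex]
  if (length(neg) == 0)
    stop("no samples of negative sex '", negative_sex, "'")
  thr <- stats::median(study$matrix[marker_gene, neg])
  message(sprintf("background threshold %.4f from %d %s samples",
                  thr, length(neg), negative_sex))
  thr
}

#' Drop genes never expressed above a background threshold
#'
#' A gene is eliminated only when its intensity is below the threshold in
#' every sample; a single sample at or above the threshold retains it (ties
#' count as expressed). Gene order and the sample set are unchanged.
#'
#' @param study An [expression_study].
#' @param threshold Background threshold on the log2 scale.
#' @return A filtered [expression_study].
#' @export
filter_unexpressed <- function(study, threshold) {
  if (!is.finite(threshold) && !identical(threshold, -Inf))
    stop("`threshold` must be finite (or -Inf for no filtering)")
  keep <- apply(study$matrix >= threshold, 1, any)
  if (!any(keep))
    warning("no genes survive the background filter", call. = FALSE)
  expression_study(study$matrix[keep, , drop = FALSE], study$samples)
}

#' Within-subject baseline correction
#'
#' Collapses each subject's pair of arrays to a single post-minus-pre log2
#' difference profile, removing inter-individual offsets. Subjects lacking a
#' complete pre/post pair are dropped with a warning (as a study would drop a
#' failed array).
#'
#' @param study An [expression_study].
#' @return A [delta_matrix] with one column per complete subject pair.
#' @export
baseline_correct <- function(study) {
  s <- study$samples
  subj <- unique(s$subject_id)
  complete <- vapply(subj, function(id) {
    tp <- s$timepoint[s$subject_id == id]
    sum(tp == "pre") == 1 && sum(tp == "post") == 1
  }, logical(1))
  if (!any(complete)) stop("no subject has a complete pre/post pair")
  if (any(!complete))
    warning("dropping subjects without complete pre/post pairs: ",
            paste(subj[!complete], collapse = ", "), call. = FALSE)
  subj <- subj[complete]
  pre_id <- vapply(subj, function(id)
    s$sample_id[s$subject_id == id & s$timepoint == "pre"], character(1))
  post_id <- vapply(subj, function(id)
    s$sample_id[s$subject_id == id & s$timepoint == "post"], character(1))
  mat <- study$matrix[, post_id, drop = FALSE] -
    study$matrix[, pre_id, drop = FALSE]
  colnames(mat) <- subj
  ann <- s[match(pre_id, s$sample_id), c("subject_id", "arm", "sex", "age")]
  delta_matrix(mat, ann)
}
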