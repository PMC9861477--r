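#' Treatment-outcome labelling from TFI scores
#'
#' Patients are labelled from the change in their Tinnitus Functional Index
#' (TFI, 0-100) between baseline and the post-treatment follow-up.  The
#' default rule follows the source protocol verbatim: change is computed as
#' post minus baseline and a patient is a responder when the change meets or
#' exceeds the smallest detectable change of 4.8 points.  Because a clinical
#' improvement is a TFI *decrease*, a `pre_minus_post` direction option is
#' provided; the default is not silently "fixed".
#'
#' @param threshold responder threshold in TFI points (> 0); default 4.8.
#' @param direction `"post_minus_pre"` (default) or `"pre_minus_post"`.
#' @return `label_spec()` returns a `tfi_label_spec` list.
#' @examples
#' label_outcome(40, 46)$label          # "responder"
#' label_outcome(40, 44.8)$label        # boundary is inclusive: "responder"
#' label_outcome(40, 44.79)$label       # "non_responder"
#' @export
label_spec <- function(threshold = 4.8,
                       direction = c("post_minus_pre", "pre_minus_post")) {
  direction <- match.arg(direction)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  structure(list(threshold = threshold, direction = direction),
            class = "tfi_label_spec")
}

#' Label one patient
#'
#' @param tfi_baseline,tfi_post TFI scores in \[0, 100\].
#' @param spec a [label_spec()].
#' @param patient_id optional identifier carried through.
#' @return A `patient_outcome` list with fields `patient_id`, `tfi_baseline`,
#'   `tfi_post`, `tfi_change` and `label`
#'   (`"responder"` or `"non_responder"`).
#' @rdname label_spec
#' @export
label_outcome <- function(tfi_baseline, tfi_post, spec = label_spec(),
                          patient_id = NA_character_) {
  stopifnot(inherits(spec, "tfi_label_spec"))
  for (v in c(tfi_baseline, tfi_post))
    if (!is.finite(v) || v < 0 || v > 100)
      stop("TFI scores must lie in [0, 100]; got ", v)
  change <- if (spec$direction == "post_minus_pre") tfi_post - tfi_baseline
            else tfi_baseline - tfi_post
  # inclusive boundary, robust to floating-point representation of scores
  responder <- change >= spec$threshold - 1e-9
  structure(list(patient_id = patient_id,
                 tfi_baseline = tfi_baseline, tfi_post = tfi_post,
                 tfi_change = change,
                 label = if (responder) "responder" else "non_responder"),
            class = "patient_outcome")
}

#' Label a whole cohort
#'
#' @param behavioural data frame with columns
#'   `patient_id,tfi_baseline,tfi_post` (see [read_behavioural()]).
#' @return data frame with added `tfi_change` and `label` columns; the two
#'   label sets always partition the cohort.
#' @rdname label_spec
#' @export
label_cohort <- function(behavioural, spec = label_spec()) {
  out <- lapply(seq_len(nrow(behavioural)), function(i)
    label_outcome(behavioural$tfi_baseline[i], behavioural$tfi_post[i],
                  spec, behavioural$patient_id[i]))
  data.frame(patient_id = vapply(out, `[[`, character(1), "patient_id"),
             tfi_baseline = behavioural$tfi_baseline,
             tfi_post = behavioural$tfi_post,
             tfi_change = vapply(out, `[[`, numeric(1), "tfi_change"),
             label = vapply(out, `[[`, character(1), "label"),
             stringsAsFactors = FALSE)
}
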