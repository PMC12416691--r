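#' Visible intervals of a fiber along its normalized axis
#'
#' A fiber is parameterized by t in \[0,1\]; the rendered part is \[0, v\]
#' (v = visibility) minus a gap of width `gap` centered at each break
#' position. Returns the remaining intervals as a 2-column matrix.
#' @keywords internal
fiber_intervals <- function(visibility, break_positions, gap) {
  if (visibility <= 0) return(matrix(numeric(0), ncol = 2))
  iv <- matrix(c(0, visibility), ncol = 2)
  for (b in break_positions) {
    lo <- b - gap / 2; hi <- b + gap / 2
    out <- matrix(numeric(0), ncol = 2)
    for (k in seq_len(nrow(iv))) {
      a <- iv[k, 1]; z <- iv[k, 2]
      if (hi <= a || lo >= z) { out <- rbind(out, c(a, z)); next }
      if (lo > a) out <- rbind(out, c(a, lo))
      if (hi < z) out <- rbind(out, c(hi, z))
    }
    iv <- out
  }
  if (nrow(iv)) iv[iv[, 2] - iv[, 1] > 1e-9, , drop = FALSE] else iv
}

#' Longest continuous visible fraction of a fiber
#'
#' @param p a [lesion_params()] with `lesion_type == "fiber"`
#' @param layout layout map (supplies the rendered gap width)
#' @return longest continuous rendered run as a fraction of full length
#' @export
longest_visible_run <- function(p, layout = phantom_layout()) {
  stopifnot(inherits(p, "lesion_params"), p$lesion_type == "fiber")
  iv <- fiber_intervals(p$visibility, p$break_positions, layout$gap_frac(p$size))
  if (!nrow(iv)) 0 else max(iv[, 2] - iv[, 1])
}

#' Guideline score implied by lesion parameters
#'
#' Applies the national QA scoring rules directly to the generative
#' parameters, yielding the ground-truth label of a rendered lesion:
#' \itemize{
#'   \item fiber: 1.0 only when the entire fiber is rendered without any
#'     break; 0.5 when the longest continuous run exceeds half the length;
#'     N/A (default) or 0.0 when something is rendered but no run exceeds
#'     half; 0.0 when nothing is rendered.
#'   \item specks: count of specks with opacity at or above the
#'     detectability floor; >= 5 scores 1.0, exactly 4 scores
#'     `config$speck_four`, 2-3 scores 0.5, <= 1 scores 0.0.
#'   \item mass: 0.0 when absent; 1.0 when more than three-quarters of the
#'     contour is circular; 0.5 otherwise.
#' }
#'
#' @param p a [lesion_params()]
#' @param config a [scoring_config()]
#' @param layout layout map
#' @return numeric score 0, 0.5 or 1, or NA for the ambiguous band
#' @export
derive_guideline_score <- function(p, config = scoring_config(),
                                   layout = phantom_layout()) {
  if (!inherits(p, "lesion_params")) stop("p must be a lesion_params object")
  switch(p$lesion_type,
    fiber = {
      run <- longest_visible_run(p, layout)
      if (p$visibility >= 1 && !length(p$break_positions)) 1.0
      else if (run > 0.5) 0.5
      else if (run > 0) if (config$fiber_short_na) NA_real_ else 0.0
      else 0.0
    },
    specks = {
      n <- sum(p$visibility >= config$speck_floor)
      if (n >= 5) 1.0
      else if (n == 4) config$speck_four
      else if (n >= 2) 0.5
      else 0.0
    },
    mass = {
      if (p$visibility <= 0) 0.0
      else if (p$visibility > config$mass_circular_fraction) 1.0
      else 0.5
    })
}

#' Ambiguity-band flags for the rule-scorer agreement protocol
#'
#' Pixel-level measurement of visibility has finite resolution, so exact
#' agreement between the rule-based scorer and the parameter-derived ground
#' truth is only claimed outside declared bands around each decision
#' boundary. The bands are part of the scoring protocol (fixed up-front):
#' fiber longest-run in (0, 0.18), (0.42, 0.58) or (0.88, 0.995); any speck
#' whose window-adjusted opacity falls in (0.22, 0.38); mass contour
#' fraction in (0.68, 0.82) or below 0.15 (nonzero).
#'
#' @param p a [lesion_params()]
#' @param layout layout map
#' @param window_gain factor by which intensity normalization rescales this
#'   phantom's contrasts relative to the calibration reference (1 = nominal)
#' @return TRUE when the lesion lies inside a declared ambiguity band
#' @export
in_ambiguity_band <- function(p, layout = phantom_layout(), window_gain = 1) {
  switch(p$lesion_type,
    fiber = {
      run <- longest_visible_run(p, layout)
      full <- p$visibility >= 1 && !length(p$break_positions)
      (run > 0 && run < 0.18) || (run > 0.42 && run < 0.58) ||
        (!full && run > 0.88)
    },
    specks = any(p$visibility * window_gain > 0.22 &
                   p$visibility * window_gain < 0.38),
    mass = (p$visibility > 0.68 && p$visibility < 0.82) ||
      (p$visibility > 0 && p$visibility < 0.15))
}
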