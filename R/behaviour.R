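#' Behaviour-rule thresholds
#'
#' Tunable knobs of the rule engine that maps coarse-grain label patterns to
#' named morphomigrational behaviours. The named behaviours come from
#' recurring archetypes in single-cell time-lapse data (gliding keratocytes,
#' laterally crawling fibroblasts, tail-retracting epithelial cells); the
#' rules are one consistent encoding of those verbal archetypes, not a
#' unique one, and every threshold below is open to adjustment.
#'
#' @param min_window Minimum window length (steps) for the stretching rules.
#' @param stretch_alpha_steps Minimum number of high/very-high turning-angle
#'   steps inside a lateral-stretching window (direction reversals along the
#'   axis).
#' @param sign_noise_deg Magnitude below which the sign of sMM or of the
#'   turning angle is treated as noise: sign changes on sub-threshold steps
#'   do not break a "constant sign" condition, and sub-threshold steps
#'   cannot establish the constant turning sign required by the gradual
#'   redirection rule.
#' @param eps_increase_tol Minimum first-to-last elongation increase for a
#'   window to count as "elongation increasing"; consecutive decreases
#'   larger than this break "non-decreasing".
#' @return A list of class `behaviour_rules`.
#' @export
behaviour_rules <- function(min_window = 3L,
                            stretch_alpha_steps = 2L,
                            sign_noise_deg = 15,
                            eps_increase_tol = 0.01) {
  structure(
    list(min_window = as.integer(min_window),
         stretch_alpha_steps = as.integer(stretch_alpha_steps),
         sign_noise_deg = sign_noise_deg,
         eps_increase_tol = eps_increase_tol),
    class = "behaviour_rules"
  )
}

behaviour_levels <- c(
  "ROUNDED_CHAOTIC", "REAR_RETRACTION", "LATERAL_U_TURN",
  "PERPENDICULAR_STRETCHING", "LATERAL_STRETCHING", "GRADUAL_REDIRECTION",
  "PERPENDICULAR_DISPLACEMENT", "ASKEW_DISPLACEMENT", "LATERAL_DISPLACEMENT",
  "UNCLASSIFIED"
)

# sign with near-zero magnitudes treated as indeterminate (0)
noisy_sign <- function(value, noise) {
  s <- sign(value)
  s[!is.na(value) & abs(value) <= noise] <- 0
  s
}

# TRUE when two (possibly indeterminate) signs are compatible
signs_agree <- function(s1, s2) {
  !is.na(s1) & !is.na(s2) & (s1 == 0 | s2 == 0 | s1 == s2)
}

#' Annotate a labelled track with morphomigrational behaviours
#'
#' Assigns one behaviour per step by the first matching rule in priority
#' order, then merges runs of identical labels into segments:
#'
#' 1. `ROUNDED_CHAOTIC` — elongation in the low band: the fitted axis is
#'    unreliable, so axis-based descriptors are uninformative.
#' 2. `REAR_RETRACTION` — |sMM| jumps from very low to high in one step
#'    while the turning angle stays low and the preceding M.A. dynamics are
#'    high/very high: the cell keeps its travel direction but its geometry
#'    flips from parallel to perpendicular.
#' 3. `LATERAL_U_TURN` — sMM very low/low with a high/very-high turning
#'    angle: reversal of travel along the major axis.
#' 4. `PERPENDICULAR_STRETCHING` — a window (>= `min_window` steps) of
#'    moderate/high sMM containing a genuine sMM sign change, with
#'    elongation increasing: protrusions on both sides of the axis.
#' 5. `LATERAL_STRETCHING` — a window of very-low/low sMM with >=
#'    `stretch_alpha_steps` high/very-high turning angles and non-decreasing
#'    elongation: repeated direction reversals along a growing axis.
#' 6. `GRADUAL_REDIRECTION` — >= 2 consecutive steps of moderate sMM with
#'    constant sign and low/moderate turning angle with constant,
#'    well-determined sign (|alpha| above `sign_noise_deg`): a slow,
#'    consistent change of direction.
#' 7. `PERPENDICULAR_DISPLACEMENT` — high sMM, sign constant with respect to
#'    the previous step, low turning angle.
#' 8. `ASKEW_DISPLACEMENT` — moderate sMM, low turning angle.
#' 9. `LATERAL_DISPLACEMENT` — very-low/low sMM, low turning angle.
#'
#' Anything else, including steps with undefined descriptors, is
#' `UNCLASSIFIED`. Rule evaluation is per-step and deterministic; a step
#' inside several qualifying windows takes the highest-priority rule that
#' covers it.
#'
#' @param labelled A labelled track from [label_track()].
#' @param rules A [behaviour_rules()] object (defaults from the track config
#'   used downstream).
#' @return `labelled` with a `behaviour` column appended, plus the attribute
#'   `"segments"`: a tibble of merged segments (`behaviour`, `start_frame`,
#'   `end_frame`, `n_steps`).
#' @export
annotate_behaviours <- function(labelled, rules = behaviour_rules()) {
  stopifnot(is.data.frame(labelled))
  need <- c("smm_label", "alpha_label", "dphi_label", "eps_label", "smm_deg",
            "turning_deg", "elongation")
  missing <- setdiff(need, names(labelled))
  if (length(missing)) {
    stop("not a labelled track; missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nrow(labelled)
  smm <- labelled$smm_label
  alpha <- labelled$alpha_label
  dphi <- labelled$dphi_label
  epsl <- labelled$eps_label
  eps <- labelled$elongation
  s_smm <- noisy_sign(labelled$smm_deg, rules$sign_noise_deg)
  s_alpha <- noisy_sign(labelled$turning_deg, rules$sign_noise_deg)

  lab <- rep(NA_character_, n)
  has_step <- !is.na(smm)   # step descriptors defined at this row

  in_set <- function(x, set) !is.na(x) & x %in% set
  alpha_low <- in_set(alpha, "low")
  alpha_high <- in_set(alpha, c("high", "very_high"))

  # rule 1: rounded shape dominates everything
  r1 <- in_set(epsl, "low") & has_step
  # rule 2: very low -> high sMM jump, low alpha, preceding dphi high
  r2 <- rep(FALSE, n)
  if (n >= 2) {
    i <- 2:n
    r2[i] <- in_set(smm[i], "high") & in_set(smm[i - 1], "very_low") &
      alpha_low[i] & in_set(dphi[i - 1], c("high", "very_high"))
  }
  # rule 3: U-turn
  r3 <- in_set(smm, c("very_low", "low")) & alpha_high
  # window rules 4 and 5
  r4 <- window_rule(n, rules$min_window, function(idx) {
    all(in_set(smm[idx], c("moderate", "high"))) &&
      has_sign_change(s_smm[idx]) &&
      eps_increasing(eps[idx], rules$eps_increase_tol)
  })
  r5 <- window_rule(n, rules$min_window, function(idx) {
    all(in_set(smm[idx], c("very_low", "low"))) &&
      sum(alpha_high[idx]) >= rules$stretch_alpha_steps &&
      eps_nondecreasing(eps[idx], rules$eps_increase_tol)
  })
  # rule 6: gradual redirection (runs of >= 2 steps)
  r6 <- rep(FALSE, n)
  if (n >= 2) {
    i <- 2:n
    ok_pair <- in_set(smm[i], "moderate") & in_set(smm[i - 1], "moderate") &
      signs_agree(s_smm[i], s_smm[i - 1]) &
      in_set(alpha[i], c("low", "moderate")) &
      in_set(alpha[i - 1], c("low", "moderate")) &
      s_alpha[i] != 0 & s_alpha[i - 1] != 0 & s_alpha[i] == s_alpha[i - 1]
    ok_pair[is.na(ok_pair)] <- FALSE
    r6[i][ok_pair] <- TRUE
    r6[i - 1][ok_pair] <- TRUE
  }
  # rule 7: perpendicular displacement (sign constant vs previous step)
  r7 <- in_set(smm, "high") & alpha_low
  if (n >= 2) {
    i <- 2:n
    prev_ok <- is.na(smm[i - 1]) | signs_agree(s_smm[i], s_smm[i - 1])
    r7[i] <- r7[i] & prev_ok
  }
  # rules 8, 9
  r8 <- in_set(smm, "moderate") & alpha_low
  r9 <- in_set(smm, c("very_low", "low")) & alpha_low

  rule_masks <- list(r1, r2, r3, r4, r5, r6, r7, r8, r9)
  for (k in seq_along(rule_masks)) {
    fire <- rule_masks[[k]] & has_step & is.na(lab)
    lab[fire] <- behaviour_levels[k]
  }
  # interior steps with no firing rule (or undefined descriptors) are
  # UNCLASSIFIED; the last frame carries no step and stays unannotated
  lab[seq_len(n - 1)][is.na(lab[seq_len(n - 1)])] <- "UNCLASSIFIED"
  lab[n] <- NA_character_

  labelled$behaviour <- lab
  attr(labelled, "segments") <- merge_segments(labelled$frame, lab)
  labelled
}

window_rule <- function(n, w, predicate) {
  out <- rep(FALSE, n)
  if (n < w) return(out)
  for (start in 1:(n - w + 1)) {
    idx <- start:(start + w - 1)
    if (isTRUE(predicate(idx))) out[idx] <- TRUE
  }
  out
}

has_sign_change <- function(s) {
  s <- s[!is.na(s) & s != 0]
  length(s) >= 2 && any(diff(s) != 0)
}

eps_increasing <- function(eps, tol) {
  if (any(is.na(eps))) return(FALSE)
  (eps[length(eps)] - eps[1]) > tol && all(diff(eps) > -tol)
}

eps_nondecreasing <- function(eps, tol) {
  if (any(is.na(eps))) return(FALSE)
  all(diff(eps) >= -tol)
}

merge_segments <- function(frame, lab) {
  keep <- !is.na(lab)
  if (!any(keep)) {
    return(tibble::tibble(behaviour = character(), start_frame = integer(),
                          end_frame = integer(), n_steps = integer()))
  }
  f <- frame[keep]
  l <- lab[keep]
  runs <- rle(l)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  tibble::tibble(
    behaviour = runs$values,
    start_frame = as.integer(f[starts]),
    end_frame = as.integer(f[ends]),
    n_steps = as.integer(runs$lengths)
  )
}

#' Census of behaviour segments
#'
#' @param annotated An annotated track from [annotate_behaviours()], or its
#'   `"segments"` attribute.
#' @param frame_interval_s Frame interval used to express durations in
#'   seconds.
#' @return Tibble with one row per behaviour present: number of segments,
#'   total steps, mean segment duration in steps and in seconds.
#' @export
behaviour_census <- function(annotated, frame_interval_s = 1) {
  segs <- if (is.data.frame(annotated) && !is.null(attr(annotated, "segments"))) {
    attr(annotated, "segments")
  } else {
    annotated
  }
  stopifnot(is.data.frame(segs))
  if (!nrow(segs)) {
    return(tibble::tibble(behaviour = character(), n_segments = integer(),
                          total_steps = integer(), mean_duration_steps = numeric(),
                          mean_duration_s = numeric()))
  }
  by_lab <- split(segs$n_steps, segs$behaviour)
  tibble::tibble(
    behaviour = names(by_lab),
    n_segments = unname(vapply(by_lab, length, integer(1))),
    total_steps = unname(vapply(by_lab, function(x) as.integer(sum(x)), integer(1))),
    mean_duration_steps = unname(vapply(by_lab, mean, numeric(1))),
    mean_duration_s = unname(vapply(by_lab, mean, numeric(1))) * frame_interval_s
  )
}
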