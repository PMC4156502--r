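#' Model-selection criteria
#'
#' Thresholds for the five-criteria assignment of a gene to the switch
#' model: the switch fit must beat the constant fit
#' (`adjR2_switch > adjR2_const`), be a good fit in absolute terms
#' (`adjR2_switch > 0.6`), the constant fit must leave room for improvement
#' (`adjR2_const < 0.9`), the switch time must fall inside an interior
#' window (12-60 min by default), and the decay-rate change must be
#' detectable (`max(k1/k2, k2/k1) > 1.4`). Genes failing all switch routes
#' are assigned to the constant model when `adjR2_const > 0.6`, otherwise
#' flagged as poor fits.
#'
#' @param min_adj_r2_switch Minimum adjusted R-squared of the switch fit.
#' @param max_adj_r2_const Switch assignment blocked when the constant fit
#'   already exceeds this.
#' @param t_switch_window Open interval (min) that must contain `t_switch`.
#' @param min_k_ratio Minimum detectable fold change in decay rate.
#' @param min_adj_r2_const Floor for assignment to the constant model.
#' @param exp_approach_floor Quality floor on the `A = 0` constant fit for
#'   flagging an exponential approach.
#' @param shift_ratio_threshold Steady-state decay-ratio threshold used by
#'   [infer_decay_shift()] (mirrors `min_k_ratio`).
#' @return List of class `"selection_criteria"`.
#' @export
selection_criteria <- function(min_adj_r2_switch = 0.6,
                               max_adj_r2_const = 0.9,
                               t_switch_window = c(12, 60),
                               min_k_ratio = 1.4,
                               min_adj_r2_const = 0.6,
                               exp_approach_floor = 0.6,
                               shift_ratio_threshold = 1.4) {
  stopifnot(min_adj_r2_switch > 0, max_adj_r2_const > 0,
            length(t_switch_window) == 2L,
            t_switch_window[1] < t_switch_window[2],
            min_k_ratio > 0, min_adj_r2_const > 0,
            shift_ratio_threshold > 1)
  structure(list(min_adj_r2_switch = min_adj_r2_switch,
                 max_adj_r2_const = max_adj_r2_const,
                 t_switch_window = t_switch_window,
                 min_k_ratio = min_k_ratio,
                 min_adj_r2_const = min_adj_r2_const,
                 exp_approach_floor = exp_approach_floor,
                 shift_ratio_threshold = shift_ratio_threshold),
            class = "selection_criteria")
}

#' Flag genes approaching a new steady state exponentially
#'
#' An instantaneous change in transcription and/or decay rate at the start
#' of the course makes abundance relax exponentially to a new steady state,
#' which the `A = 0` constant variant (`B + C exp(-k t)`) captures exactly.
#' The flag is set when the `A = 0` fit strictly beats the full constant fit
#' on adjusted R-squared and itself clears the quality floor.
#'
#' @param fit_full Full constant-model `"kinetic_fit"`.
#' @param fit_a0 `A = 0` constant-model `"kinetic_fit"`.
#' @param floor Minimum adjusted R-squared for the `A = 0` fit.
#' @return Logical flag.
#' @export
flag_exponential_approach <- function(fit_full, fit_a0, floor = 0.6) {
  a0 <- fit_a0$diagnostics$adj_r2
  (a0 > fit_full$diagnostics$adj_r2) && (a0 > floor)
}

#' Infer a decay-rate shift from steady-state plateaus
#'
#' At steady state abundance balances production over decay (`E = R/k`), so
#' the ratio of initial to final decay constants follows from the measured
#' fold changes: `k_I / k_F = (E_F / E_I) / (R_F / R_I)`. Ratios above the
#' threshold are called stabilized (slower decay after the shift), below
#' its reciprocal destabilized.
#'
#' @param y_initial,y_final Expression plateaus before/after the transition
#'   (linear scale, > 0).
#' @param f_initial,f_final Transcription-rate plateaus (linear scale, > 0).
#' @param threshold Ratio threshold for calling a shift (default 1.4).
#' @return List with `ratio` (`k_I / k_F`) and `label`
#'   (`"stabilized"`, `"destabilized"`, or `"none"`).
#' @examples
#' infer_decay_shift(1, 2, 1, 1) # pure 2x stabilization
#' @export
infer_decay_shift <- function(y_initial, y_final, f_initial, f_final,
                              threshold = 1.4) {
  v <- c(y_initial, y_final, f_initial, f_final)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("steady-state plateau estimates must be positive")
  ratio <- (y_final / y_initial) / (f_final / f_initial)
  label <- if (ratio > threshold) "stabilized"
           else if (ratio < 1 / threshold) "destabilized"
           else "none"
  list(ratio = ratio, label = label)
}

switch_criteria_pass <- function(sw, adj_const, criteria) {
  d <- sw$diagnostics
  k1 <- sw$params[["k1"]]
  k2 <- sw$params[["k2"]]
  ts <- sw$params[["t_switch"]]
  (d$adj_r2 > adj_const) &&
    (d$adj_r2 > criteria$min_adj_r2_switch) &&
    (adj_const < criteria$max_adj_r2_const) &&
    (ts > criteria$t_switch_window[1]) &&
    (ts < criteria$t_switch_window[2]) &&
    (max(k1 / k2, k2 / k1) > criteria$min_k_ratio)
}

#' Assign a gene to the switch, constant, or poor-fit class
#'
#' Applies the five selection criteria (see [selection_criteria()]) to the
#' full (`A >= 0`) switch fit; if it fails, the `A = 0` switch fit is tested
#' against the same criteria; failing both, the gene is assigned to the
#' constant model when its adjusted R-squared clears the floor, and
#' otherwise declared a poor fit. The constant-fit reference is the better
#' of the full and `A = 0` constant fits (conservative against false switch
#' calls). Exact ties between switch and constant go to the constant model
#' (parsimony).
#'
#' @param fits Named list with elements `constant`, `constant_a0`,
#'   `switch`, and `switch_a0`, each a `"kinetic_fit"`.
#' @param criteria A [selection_criteria()] object.
#' @param pair Optional [time_course_pair()]; when supplied, a decay shift
#'   is inferred for exponential-approach genes from the profile plateaus
#'   (first point vs last point) via [infer_decay_shift()].
#' @param gene_id Identifier recorded in the assignment.
#' @return List of class `"model_assignment"`: `assigned` (one of
#'   `"switch"`, `"constant"`, `"poor_fit"`), `used_a_zero`,
#'   `exp_approach`, `decay_shift` (`"stabilized"`, `"destabilized"`, or
#'   `"none"`), `half_lives` (pre/post, min), and the adjusted R-squared of
#'   each fit.
#' @export
select_model <- function(fits, criteria = selection_criteria(), pair = NULL,
                         gene_id = NULL) {
  need <- c("constant", "constant_a0", "switch", "switch_a0")
  if (!all(need %in% names(fits)))
    stop("fits must contain: ", paste(need, collapse = ", "))
  adj <- vapply(fits[need], function(f) f$diagnostics$adj_r2, numeric(1))
  adj_const <- max(adj[["constant"]], adj[["constant_a0"]])
  assigned <- NULL
  used_a_zero <- FALSE
  sel <- NULL
  if (switch_criteria_pass(fits$switch, adj_const, criteria)) {
    assigned <- "switch"
    sel <- fits$switch
  } else if (switch_criteria_pass(fits$switch_a0, adj_const, criteria)) {
    assigned <- "switch"
    used_a_zero <- TRUE
    sel <- fits$switch_a0
  } else if (adj_const > criteria$min_adj_r2_const) {
    assigned <- "constant"
    used_a_zero <- adj[["constant_a0"]] > adj[["constant"]]
    sel <- if (used_a_zero) fits$constant_a0 else fits$constant
  } else {
    assigned <- "poor_fit"
    used_a_zero <- adj[["constant_a0"]] > adj[["constant"]]
    sel <- if (used_a_zero) fits$constant_a0 else fits$constant
  }
  exp_approach <- FALSE
  decay_shift <- "none"
  shift_ratio <- NA_real_
  half_lives <- c(pre = NA_real_, post = NA_real_)
  if (assigned == "switch") {
    k1 <- sel$params[["k1"]]
    k2 <- sel$params[["k2"]]
    half_lives <- c(pre = half_life(k1), post = half_life(k2))
    decay_shift <- if (k2 < k1) "stabilized" else "destabilized"
    shift_ratio <- k1 / k2
  } else if (assigned == "constant") {
    k <- sel$params[["k"]]
    half_lives <- c(pre = half_life(k), post = half_life(k))
    exp_approach <- flag_exponential_approach(fits$constant,
                                              fits$constant_a0,
                                              criteria$exp_approach_floor)
    if (exp_approach && !is.null(pair)) {
      n <- length(pair$y)
      shift <- infer_decay_shift(pair$y[1], pair$y[n], pair$f[1], pair$f[n],
                                 criteria$shift_ratio_threshold)
      decay_shift <- shift$label
      shift_ratio <- shift$ratio
    }
  }
  structure(list(gene_id = gene_id %||% "gene", assigned = assigned,
                 used_a_zero = used_a_zero, exp_approach = exp_approach,
                 decay_shift = decay_shift, shift_ratio = shift_ratio,
                 half_lives = half_lives,
                 adj_r2 = c(constant = adj[["constant"]],
                            constant_a0 = adj[["constant_a0"]],
                            switch = adj[["switch"]],
                            switch_a0 = adj[["switch_a0"]])),
            class = "model_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.model_assignment <- function(x, ...) {
  cat(sprintf("Gene %s: assigned '%s'%s\n", x$gene_id, x$assigned,
              if (x$used_a_zero) " (A = 0 variant)" else ""))
  cat("  adj R^2:",
      paste(sprintf("%s %.3f", names(x$adj_r2), x$adj_r2), collapse = ", "),
      "\n")
  if (x$assigned == "switch" || x$exp_approach)
    cat(sprintf("  decay shift: %s; half-lives %.1f -> %.1f min\n",
                x$decay_shift, x$half_lives["pre"], x$half_lives["post"]))
  if (x$exp_approach)
    cat("  exponential approach to a new steady state\n")
  invisible(x)
}
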