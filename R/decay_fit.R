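#' Fit the kinetic decay models to one gene
#'
#' The central fitting routine: fits the constant-decay model (full and
#' `A = 0` variants) and the piecewise switch-decay model (full and `A = 0`)
#' to a paired relative transcription/expression time course, then applies
#' the five-criteria model selection ([select_model()]) and infers the
#' decay-rate shift. Profiles with missing time points or no variation in
#' expression are not fitted and are returned with assignment
#' `"uninformative"`.
#'
#' @param pair A [time_course_pair()], or a numeric vector of expression
#'   values (then `f` and `time` must be given).
#' @param f,time Rate profile and time grid when `pair` is a plain vector.
#' @param gene_id Gene identifier.
#' @param options A [fit_options()] object.
#' @param criteria A [selection_criteria()] object.
#' @param input Scale of plain-vector input (`"linear"` or `"log2"`).
#' @return An object of class `"decay_fit"`: the data, the four
#'   `"kinetic_fit"`s, and the `"model_assignment"`. Supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()`, and `plot()`.
#' @examples
#' tt <- c(0, 5, 10, 16, 25, 33, 41, 48, 60, 80, 100, 120)
#' f <- impulse_rate(1, 4, 1.2, 5, 40, 0.5)(tt)
#' y <- simulate_abundance(f, c(k = 0.03), E0 = f[1] / 0.03, time = tt)
#' fit <- decay_fit(time_course_pair(tt, f / mean(f), y / mean(y)))
#' fit
#' @export
decay_fit <- function(pair, f = NULL, time = NULL, gene_id = "gene",
                      options = fit_options(),
                      criteria = selection_criteria(),
                      input = c("linear", "log2")) {
  if (!inherits(pair, "time_course_pair")) {
    input <- match.arg(input)
    pair <- time_course_pair(time, f, pair, gene_id = gene_id, input = input)
  }
  status <- check_fittable(pair)
  if (status != "ok") {
    return(structure(list(pair = pair, fits = NULL,
                          assignment = list(gene_id = pair$gene_id,
                                            assigned = "uninformative",
                                            reason = status),
                          options = options, criteria = criteria),
                     class = "decay_fit"))
  }
  fits <- list(constant = fit_constant(pair, options, a_zero = FALSE),
               constant_a0 = fit_constant(pair, options, a_zero = TRUE),
               switch = fit_switch(pair, options, a_zero = FALSE),
               switch_a0 = fit_switch(pair, options, a_zero = TRUE))
  assignment <- select_model(fits, criteria, pair = pair,
                             gene_id = pair$gene_id)
  structure(list(pair = pair, fits = fits, assignment = assignment,
                 options = options, criteria = criteria),
            class = "decay_fit")
}

# the kinetic_fit backing the reported parameters: the switch variant that
# passed selection, else the better constant variant
selected_fit <- function(object) {
  if (is.null(object$fits)) return(NULL)
  a <- object$assignment
  if (a$assigned == "switch") {
    if (a$used_a_zero) object$fits$switch_a0 else object$fits$switch
  } else {
    if (isTRUE(a$used_a_zero)) object$fits$constant_a0 else object$fits$constant
  }
}

resolve_model <- function(object, model) {
  model <- match.arg(model, c("selected", "constant", "constant_a0",
                              "switch", "switch_a0"))
  if (model == "selected") selected_fit(object) else object$fits[[model]]
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Kinetic decay-model fit for gene '%s'\n", x$pair$gene_id))
  if (is.null(x$fits)) {
    cat(sprintf("  uninformative (%s data)\n", x$assignment$reason))
    return(invisible(x))
  }
  a <- x$assignment
  cat(sprintf("  assigned: %s%s\n", a$assigned,
              if (a$used_a_zero) " (A = 0 variant)" else ""))
  sel <- selected_fit(x)
  print(signif(sel$params, 4))
  cat("  adj R^2:",
      paste(sprintf("%s %.3f", names(a$adj_r2), a$adj_r2), collapse = ", "),
      "\n")
  if (a$assigned == "switch")
    cat(sprintf("  decay %s at t = %.1f min (half-life %.1f -> %.1f min)\n",
                a$decay_shift, sel$params[["t_switch"]],
                a$half_lives["pre"], a$half_lives["post"]))
  if (isTRUE(a$exp_approach))
    cat(sprintf("  exponential approach to new steady state (shift: %s)\n",
                a$decay_shift))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.decay_fit")
}

#' @export
print.summary.decay_fit <- function(x, ...) {
  object <- x$fit
  print(object)
  if (is.null(object$fits)) return(invisible(x))
  cat("\nAll model variants:\n")
  tab <- do.call(rbind, lapply(object$fits, function(f) {
    d <- f$diagnostics
    data.frame(model = f$model, a_zero = f$a_zero, sse = d$sse, p = d$p,
               adj_r2 = d$adj_r2, converged = d$converged,
               n_iter = d$n_iter)
  }))
  print(tab, digits = 4)
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, model = "selected", ...) {
  fit <- resolve_model(object, model)
  if (is.null(fit)) return(NULL)
  fit$params
}

#' Predict expression from a fitted kinetic model
#'
#' @param object A `"decay_fit"`.
#' @param times Evaluation times (min) within the grid span; defaults to
#'   the sampling grid.
#' @param model Which fitted variant to evaluate (default the selected one).
#' @param scale `"linear"` relative ratios or `"log2"`.
#' @param ... Unused.
#' @return Predicted relative expression at `times`.
#' @export
predict.decay_fit <- function(object, times = NULL, model = "selected",
                              scale = c("linear", "log2"), ...) {
  scale <- match.arg(scale)
  fit <- resolve_model(object, model)
  if (is.null(fit)) stop("no fits available (uninformative gene)")
  times <- times %||% object$pair$time
  yhat <- if (fit$model == "constant") {
    forward_constant(fit$params, object$pair$f, object$pair$time, times)
  } else {
    forward_switch(fit$params, object$pair$f, object$pair$time, times)
  }
  if (scale == "log2") log2(pmax(yhat, .Machine$double.eps)) else yhat
}

#' @export
fitted.decay_fit <- function(object, model = "selected", ...) {
  predict(object, model = model)
}

#' @export
residuals.decay_fit <- function(object, model = "selected", ...) {
  object$pair$y - fitted(object, model = model)
}

#' Simulate noisy expression replicates from a fitted model
#'
#' Draws replicates of the expression profile from the selected model with
#' multiplicative log-normal noise; the log2 noise sd defaults to the sd of
#' the log2 residuals of the fit.
#'
#' @param object A `"decay_fit"`.
#' @param nsim Number of replicates.
#' @param seed Optional integer seed.
#' @param sd_log2 Noise sd in log2 units.
#' @param ... Unused.
#' @return Matrix with `nsim` rows of linear relative expression profiles.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL,
                               sd_log2 = NULL, ...) {
  mu <- fitted(object)
  if (is.null(sd_log2))
    sd_log2 <- sd(log2(pmax(object$pair$y, .Machine$double.eps)) -
                  log2(pmax(mu, .Machine$double.eps)))
  with_seed(seed, function() {
    t(vapply(seq_len(nsim),
             function(i) mu * 2^rnorm(length(mu), 0, sd_log2),
             numeric(length(mu))))
  })
}

#' Plot data and fitted kinetic models for one gene
#'
#' Shows the measured expression profile (log2), the measured
#' transcription-rate profile, and the fitted constant and switch model
#' curves; the estimated switch time is marked when the gene is assigned to
#' the switch model.
#'
#' @param x A `"decay_fit"`.
#' @param ... Passed to `plot()`.
#' @export
plot.decay_fit <- function(x, ...) {
  if (is.null(x$fits)) stop("nothing to plot for an uninformative gene")
  p <- x$pair
  tfine <- seq(0, max(p$time), length.out = 200)
  yc <- log2(pmax(predict(x, tfine, model = "constant"), 1e-12))
  ys <- log2(pmax(predict(x, tfine, model = "switch"), 1e-12))
  ylim <- range(log2(p$y), log2(p$f), yc, ys, finite = TRUE)
  plot(p$time, log2(p$y), pch = 19, xlab = "time (min)",
       ylab = "log2 relative level", ylim = ylim,
       main = sprintf("%s ('%s')", p$gene_id, x$assignment$assigned), ...)
  points(p$time, log2(p$f), pch = 1, col = "grey50")
  lines(p$time, log2(p$f), lty = 3, col = "grey50")
  lines(tfine, yc, col = "steelblue", lwd = 2)
  lines(tfine, ys, col = "firebrick", lwd = 2, lty = 2)
  if (x$assignment$assigned == "switch") {
    sel <- selected_fit(x)
    abline(v = sel$params[["t_switch"]], col = "firebrick", lty = 3)
  }
  legend("topright", bty = "n", cex = 0.8,
         legend = c("expression (y)", "transcription (f)", "constant fit",
                    "switch fit"),
         col = c("black", "grey50", "steelblue", "firebrick"),
         pch = c(19, 1, NA, NA), lty = c(NA, 3, 1, 2))
  invisible(x)
}

#' Fit the kinetic models across a cohort of genes
#'
#' Applies [decay_fit()] to every gene of a cohort and tabulates the
#' outcome: model assignment, fitted parameters of the selected model,
#' adjusted R-squared of each variant, half-lives, exponential-approach
#' flag, and decay-shift direction. Genes with missing time points are not
#' fitted (`"uninformative"`).
#'
#' @param f Gene-by-time matrix of log2-ratio transcription-rate profiles,
#'   or a `"stress_cohort"` from [simulate_cohort()] (then `y` and `time`
#'   are taken from it).
#' @param y Gene-by-time matrix of log2-ratio expression profiles.
#' @param time Shared time grid (min).
#' @param options A [fit_options()] object.
#' @param criteria A [selection_criteria()] object.
#' @return A `data.frame` of class `"decay_fit_table"`, one row per gene
#'   with columns `gene_id, assigned, used_a_zero, A, B, C, k, k1, k2,
#'   t_switch, adj_r2_const, adj_r2_const_a0, adj_r2_switch, half_life_pre,
#'   half_life_post, exp_approach, decay_shift, converged`.
#' @export
fit_decay_models <- function(f, y = NULL, time = NULL,
                             options = fit_options(),
                             criteria = selection_criteria()) {
  if (inherits(f, "stress_cohort")) {
    time <- f$time
    y <- f$y
    f <- f$f
  }
  stopifnot(is.matrix(f), is.matrix(y), all(dim(f) == dim(y)))
  check_time_grid(time)
  ids <- rownames(f) %||% sprintf("g%04d", seq_len(nrow(f)))
  rows <- vector("list", nrow(f))
  for (i in seq_len(nrow(f))) {
    fi <- f[i, ]
    yi <- y[i, ]
    complete <- !anyNA(fi) && !anyNA(yi)
    if (!complete) {
      rows[[i]] <- fit_row_na(ids[i], "uninformative")
      next
    }
    pair <- time_course_pair(time, fi, yi, gene_id = ids[i], input = "log2")
    fit <- decay_fit(pair, options = options, criteria = criteria)
    rows[[i]] <- fit_row(fit)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "options") <- options
  attr(out, "criteria") <- criteria
  class(out) <- c("decay_fit_table", "data.frame")
  out
}

fit_row_na <- function(id, assigned) {
  data.frame(gene_id = id, assigned = assigned, used_a_zero = NA,
             A = NA_real_, B = NA_real_, C = NA_real_, k = NA_real_,
             k1 = NA_real_, k2 = NA_real_, t_switch = NA_real_,
             adj_r2_const = NA_real_, adj_r2_const_a0 = NA_real_,
             adj_r2_switch = NA_real_, half_life_pre = NA_real_,
             half_life_post = NA_real_, exp_approach = NA,
             decay_shift = NA_character_, converged = NA,
             stringsAsFactors = FALSE)
}

fit_row <- function(fit) {
  a <- fit$assignment
  if (a$assigned == "uninformative")
    return(fit_row_na(a$gene_id, "uninformative"))
  sel <- selected_fit(fit)
  is_switch <- a$assigned == "switch"
  adj_sw <- if (is_switch) {
    a$adj_r2[[if (a$used_a_zero) "switch_a0" else "switch"]]
  } else {
    max(a$adj_r2[["switch"]], a$adj_r2[["switch_a0"]])
  }
  data.frame(gene_id = a$gene_id, assigned = a$assigned,
             used_a_zero = a$used_a_zero,
             A = sel$params[["A"]], B = sel$params[["B"]],
             C = sel$params[["C"]],
             k = if (is_switch) NA_real_ else sel$params[["k"]],
             k1 = if (is_switch) sel$params[["k1"]] else NA_real_,
             k2 = if (is_switch) sel$params[["k2"]] else NA_real_,
             t_switch = if (is_switch) sel$params[["t_switch"]] else NA_real_,
             adj_r2_const = a$adj_r2[["constant"]],
             adj_r2_const_a0 = a$adj_r2[["constant_a0"]],
             adj_r2_switch = adj_sw,
             half_life_pre = a$half_lives[["pre"]],
             half_life_post = a$half_lives[["post"]],
             exp_approach = a$exp_approach, decay_shift = a$decay_shift,
             converged = sel$diagnostics$converged,
             stringsAsFactors = FALSE)
}

#' @export
print.decay_fit_table <- function(x, ...) {
  cat(sprintf("Kinetic decay-model fits: %d genes\n", nrow(x)))
  print(table(x$assigned))
  if (any(x$assigned == "constant", na.rm = TRUE))
    cat(sprintf("exponential-approach genes: %d\n",
                sum(x$exp_approach, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.decay_fit_table <- function(object, ...) {
  counts <- table(object$assigned)
  sw <- object[object$assigned == "switch", , drop = FALSE]
  out <- list(n = nrow(object), counts = counts,
              n_exp_approach = sum(object$exp_approach, na.rm = TRUE),
              switch_shift = table(sw$decay_shift),
              median_half_life = median(object$half_life_pre, na.rm = TRUE))
  class(out) <- "summary.decay_fit_table"
  out
}

#' @export
print.summary.decay_fit_table <- function(x, ...) {
  cat(sprintf("Cohort of %d genes\n", x$n))
  pct <- 100 * x$counts / sum(x$counts)
  for (nm in names(x$counts))
    cat(sprintf("  %-13s %5d (%.1f%%)\n", nm, x$counts[[nm]], pct[[nm]]))
  cat(sprintf("  exponential-approach flagged: %d\n", x$n_exp_approach))
  if (length(x$switch_shift))
    cat("  switch direction:",
        paste(sprintf("%s %d", names(x$switch_shift), x$switch_shift),
              collapse = ", "), "\n")
  cat(sprintf("  median fitted half-life: %.1f min\n", x$median_half_life))
  invisible(x)
}
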