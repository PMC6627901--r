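#' Four-parameter logistic viability model
#'
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`: viability falls
#' from `top` at low concentration to `bottom` at high concentration when
#' `hill > 0`.
#'
#' @param conc Concentrations (molar, positive).
#' @param top,bottom Upper/lower viability asymptotes (fractions).
#' @param ic50 Concentration of half-maximal fitted effect (molar).
#' @param hill Hill slope.
#' @return Viability fractions.
#' @export
four_pl <- function(conc, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + (conc / ic50)^hill)
}

#' Normalize raw plate signal to a viability fraction
#'
#' `(signal - blank) / (control - blank)`, clipped to `clip` to absorb
#' fluorescence overshoot below blank or above control.
#'
#' @param signal,control_signal,blank_signal Raw plate readings; controls are
#'   untreated wells, blanks cell-free wells. `control_signal` must exceed
#'   `blank_signal`.
#' @param clip Lower/upper clipping bounds for the fraction.
#' @return Viability fractions in `[clip[1], clip[2]]`.
#' @examples
#' normalize_viability(550, 1050, 50) # 0.5
#' @export
normalize_viability <- function(signal, control_signal, blank_signal,
                                clip = c(-0.05, 1.2)) {
  if (any(control_signal <= blank_signal)) {
    abort("`control_signal` must exceed `blank_signal`")
  }
  v <- (signal - blank_signal) / (control_signal - blank_signal)
  pmin(pmax(v, clip[1]), clip[2])
}

#' Trapezoidal response AUC over log10 concentration
#'
#' `auc_raw` integrates the observed viability fraction over
#' log10(concentration / M) by the trapezoid rule; `auc_norm` divides by the
#' log10 span of the tested range so a completely unresponsive curve scores
#' 1. Lower values mean greater sensitivity.
#'
#' @param concentrations Strictly increasing positive molar concentrations
#'   (at least 2).
#' @param viability Viability fractions at those concentrations.
#' @return A list with `auc_raw` and `auc_norm`.
#' @examples
#' compute_response_auc(c(0.5e-9, 3e-5), c(1, 1)) # auc_norm = 1
#' @export
compute_response_auc <- function(concentrations, viability) {
  if (length(concentrations) < 2) abort("need at least 2 concentrations")
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  if (is.unsorted(concentrations, strictly = TRUE)) {
    abort("concentrations must be strictly increasing")
  }
  lc <- log10(concentrations)
  auc_raw <- sum(diff(lc) * (utils::head(viability, -1) +
                               utils::tail(viability, -1)) / 2)
  list(auc_raw = auc_raw, auc_norm = auc_raw / (max(lc) - min(lc)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of [four_pl()] on the log10 concentration axis via
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]) with deterministic multi-start
#' initialization: hill started at 0.5, 1 and 2, IC50 at the concentration
#' whose viability is nearest the half-range; the start with the lowest
#' residual sum of squares wins. Degenerate inputs (flat viability, failed
#' optimization, IC50 far outside the tested range) yield `converged = FALSE`
#' while the model-free AUC descriptors are still computed.
#'
#' @param concentrations At least 4 distinct positive molar concentrations,
#'   strictly increasing.
#' @param viability Replicate-averaged viability fractions.
#' @param cell_line,drug Optional labels carried into the result.
#' @return An object of class `dr_fit` with elements `top`, `bottom`,
#'   `ic50`, `hill`, `auc_raw`, `auc_norm`, `fit_r`, `converged`, `data`.
#' @examples
#' conc <- 0.5e-9 * 2.5^(0:12)
#' fit <- fit_4pl(conc, four_pl(conc, 1, 0, 1e-6, 1))
#' round(fit$ic50 / 1e-6, 3)
#' @export
fit_4pl <- function(concentrations, viability, cell_line = NA_character_,
                    drug = NA_character_) {
  if (length(concentrations) < 4) abort("need at least 4 concentrations to fit")
  if (length(viability) != length(concentrations)) {
    abort("`viability` and `concentrations` lengths differ")
  }
  if (!all(is.finite(viability))) abort("viabilities must be finite")
  if (any(concentrations <= 0)) abort("concentrations must be positive")
  o <- order(concentrations)
  concentrations <- concentrations[o]
  viability <- viability[o]
  auc <- compute_response_auc(concentrations, viability)
  out <- list(
    cell_line = cell_line, drug = drug,
    top = max(viability), bottom = min(viability),
    ic50 = NA_real_, hill = NA_real_,
    auc_raw = auc$auc_raw, auc_norm = auc$auc_norm,
    fit_r = NA_real_, converged = FALSE, message = "",
    data = tibble(concentration_M = concentrations, viability = viability,
                  fitted = NA_real_)
  )
  if (stats::sd(viability) == 0) {
    out$message <- "flat viability; 4PL undetermined"
    out$top <- out$bottom <- viability[1]
    out$data$fitted <- viability
    out$fit_r <- NA_real_
    return(structure(out, class = "dr_fit"))
  }
  lc <- log10(concentrations)
  half <- (max(viability) + min(viability)) / 2
  lic50_start <- lc[which.min(abs(viability - half))]
  df <- data.frame(lc = lc, v = viability)
  best <- NULL
  for (hill0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ bottom + (top - bottom) / (1 + 10^(hill * (lc - lic50))),
        data = df,
        start = list(top = max(viability), bottom = min(viability),
                     lic50 = lic50_start, hill = hill0),
        lower = c(top = -0.5, bottom = -0.5, lic50 = min(lc) - 6, hill = 0.01),
        upper = c(top = 1.5, bottom = 1.5, lic50 = max(lc) + 6, hill = 20),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out$message <- "optimization failed for every start"
    return(structure(out, class = "dr_fit"))
  }
  cf <- stats::coef(best$fit)
  # enforce bottom <= top (the logistic is symmetric under the swap
  # top<->bottom, hill -> -hill; with hill constrained positive the optimum
  # always lands in the decreasing branch, but guard anyway)
  if (cf[["bottom"]] > cf[["top"]]) {
    tmp <- cf[["top"]]; cf[["top"]] <- cf[["bottom"]]; cf[["bottom"]] <- tmp
  }
  fitted <- four_pl(concentrations, cf[["top"]], cf[["bottom"]],
                    10^cf[["lic50"]], cf[["hill"]])
  out$top <- cf[["top"]]
  out$bottom <- cf[["bottom"]]
  out$ic50 <- 10^cf[["lic50"]]
  out$hill <- cf[["hill"]]
  out$data$fitted <- fitted
  out$fit_r <- stats::cor(fitted, viability)
  in_range <- out$ic50 >= min(concentrations) / 1e3 &&
    out$ic50 <= max(concentrations) * 1e3
  out$converged <- in_range
  if (!in_range) out$message <- "fitted IC50 outside plausible range"
  structure(out, class = "dr_fit")
}

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit>", x$cell_line, "/", x$drug,
      sprintf("ic50=%.3g M hill=%.2f auc_norm=%.3f fit_r=%.4f %s\n",
              x$ic50, x$hill, x$auc_norm, x$fit_r,
              if (x$converged) "converged" else paste0("NOT converged (",
                                                       x$message, ")")))
  invisible(x)
}

#' Fit every dose-response curve on a plate
#'
#' Tidy front end for screening data: normalizes raw signals with
#' [normalize_viability()], averages technical replicates per concentration,
#' and fits each (cell line, drug) series with [fit_4pl()].
#'
#' @param plate Long plate tibble with columns `cell_line`, `drug`,
#'   `concentration_M`, `signal`, `control_signal`, `blank_signal` (the
#'   schema written by [simulate_dose_response()]).
#' @param clip Viability clipping bounds passed to [normalize_viability()].
#' @param keep_fits Keep the underlying `dr_fit` objects in a list column?
#' @return A tibble with one row per (cell line, drug): `top`, `bottom`,
#'   `ic50_M`, `hill`, `auc_raw`, `auc_norm`, `fit_r`, `converged`.
#' @export
fit_dose_response <- function(plate, clip = c(-0.05, 1.2), keep_fits = FALSE) {
  plate <- as_tibble(plate)
  need <- c("cell_line", "drug", "concentration_M", "signal",
            "control_signal", "blank_signal")
  if (!all(need %in% names(plate))) {
    abort(paste("plate is missing columns:",
                paste(setdiff(need, names(plate)), collapse = ", ")))
  }
  curves <- plate |>
    dplyr::mutate(viability = normalize_viability(
      .data$signal, .data$control_signal, .data$blank_signal, clip = clip
    )) |>
    dplyr::summarise(
      viability = mean(.data$viability),
      .by = c("cell_line", "drug", "concentration_M")
    ) |>
    dplyr::arrange(.data$cell_line, .data$drug, .data$concentration_M)
  fits <- curves |>
    tidyr::nest(.by = c("cell_line", "drug")) |>
    dplyr::mutate(fit = purrr::pmap(
      list(.data$cell_line, .data$drug, .data$data),
      function(cl, dr, d) fit_4pl(d$concentration_M, d$viability,
                                  cell_line = cl, drug = dr)
    ))
  out <- fits |>
    dplyr::mutate(res = purrr::map(.data$fit, glance)) |>
    dplyr::select(-"data") |>
    tidyr::unnest("res")
  if (!keep_fits) out <- dplyr::select(out, -"fit")
  out
}
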