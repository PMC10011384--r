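# Water-referenced calibration and parameter fitting.

#' Calibrate the strength coefficients against water
#'
#' Builds water from SMILES `"O"`, embeds and MMFF94-minimises it with the
#' given seed, computes backend charges, and solves the two one-point
#' calibration conditions: `D = 1 / (qH + delta_qH)` (mean over the two
#' hydrogens) and `A = 1 / (qO + delta_qO)`, so that the water hydrogens
#' and oxygen score donor/acceptor strength exactly 1.0.
#'
#' @param backend Charge backend name (see [compute_charges_radii()]).
#' @param seed Embedding seed.
#' @param T Bond reduction factor used in the corrective term.
#' @return Object of class `water_calibration`: list with `D`, `A`, `T`,
#'   the underlying corrected charge sums, and the prepared water record.
#' @export
calibrate_water <- function(backend = "eeq", seed = 1L, T = 0.274) {
  water <- load_molecules(textConnection_file("O water"), "smiles")[[1]]
  water <- prepare_conformer(water, seed = seed)
  water <- compute_charges_radii(water, backend = backend)
  h_idx <- which(water$atoms$element == "H")
  o_idx <- which(water$atoms$element == "O")
  dist <- topo_distances(water)
  f_h <- mean(vapply(h_idx, function(i) {
    water$atoms$q[i] + delta_q(i, water, T, dist)
  }, numeric(1)))
  f_o <- water$atoms$q[o_idx] + delta_q(o_idx, water, T, dist)
  if (abs(f_h) < 1e-12 || abs(f_o) < 1e-12) {
    stop("calibration error: degenerate corrected charges on water",
         call. = FALSE)
  }
  structure(list(D = 1 / f_h, A = 1 / f_o, T = T,
                 qH_corrected = f_h, qO_corrected = f_o,
                 backend = water$backend, water = water),
            class = "water_calibration")
}

#' @export
print.water_calibration <- function(x, ...) {
  cat(sprintf("<water_calibration> backend %s\n", x$backend))
  cat(sprintf("  D = %.4f  (qH + dqH = %.6f)\n", x$D, x$qH_corrected))
  cat(sprintf("  A = %.4f  (qO + dqO = %.6f)\n", x$A, x$qO_corrected))
  invisible(x)
}

# write a one-off temp file from a string (load_molecules wants a path)
textConnection_file <- function(text) {
  f <- tempfile(fileext = ".smi")
  writeLines(text, f)
  f
}

#' Default sign-preserving fitting bounds
#'
#' Each free parameter may move within one decade either side of its
#' reference value, keeping its sign.
#'
#' @param params Reference [hydration_params()].
#' @return Named list of `c(lower, upper)` bounds.
#' @export
default_search_space <- function(params = hydration_params()) {
  out <- lapply(free_param_names(), function(nm) {
    v <- params[[nm]]
    sort(c(v / 10, v * 10))
  })
  names(out) <- free_param_names()
  out
}

#' Fit the free hydration parameters against experimental data
#'
#' Minimises the mean absolute error (MAE) between predicted and
#' experimental hydration free energies over the eleven free parameters;
#' the calibration constants D, A, T stay fixed, so geometries, charges
#' and strengths are computed once and every trial is a cheap re-scoring.
#'
#' The seeded sampler proposes the three nonlinear parameters (`exp_d`,
#' `exp_a`, `F`) by a mix of local log-normal perturbation around the
#' incumbent and uniform draws inside the bounds, and solves the eight
#' linear coefficients by least squares conditional on them. The search
#' stops when `patience` consecutive trials fail to improve the best MAE.
#'
#' @param records List of prepared `mol_record` (charges are computed on
#'   the fly if missing).
#' @param dg_exp Numeric vector of experimental energies, kJ/mol.
#' @param params0 Starting parameter set.
#' @param search_space Named list of per-parameter bounds, as
#'   [default_search_space()].
#' @param patience Early-stop cycles without improvement (default 300).
#' @param max_trials Hard cap on trials.
#' @param seed Integer seed; runs are deterministic given
#'   (data, seed).
#' @param donor_scope,donor_aggregation See [polar_term()].
#' @return Object of class `fit_result`: `best_params`, `best_mae`,
#'   `n_trials`, `trial_log` (data.frame), `seed`.
#' @export
fit_parameters <- function(records, dg_exp, params0 = hydration_params(),
                           search_space = default_search_space(params0),
                           patience = 300, max_trials = 5000, seed = 1L,
                           donor_scope = "xh-only",
                           donor_aggregation = "mean") {
  if (!length(records)) stop("empty dataset", call. = FALSE)
  stopifnot(length(records) == length(dg_exp), is.numeric(dg_exp))
  feats <- list()
  kept <- logical(length(records))
  for (k in seq_along(records)) {
    f <- tryCatch({
      r <- records[[k]]
      if (anyNA(r$atoms$q)) r <- compute_charges_radii(r)
      s <- molecular_strengths(r, params0$strength)
      hydration_features(r, s, donor_scope, donor_aggregation)
    }, error = identity)
    if (!inherits(f, "error")) {
      feats[[length(feats) + 1]] <- f
      kept[k] <- TRUE
    }
  }
  if (!length(feats)) stop("data error: no molecule could be prepared",
                           call. = FALSE)
  dg_exp <- dg_exp[kept]

  # design columns that do not depend on any free parameter
  base <- data.frame(
    const = rep(1, length(feats)),
    N_s = vapply(feats, `[[`, numeric(1), "N_s"),
    N_r = vapply(feats, function(f) as.numeric(f$N_r), numeric(1)),
    N_pi2 = vapply(feats, function(f) as.numeric(f$N_pi2), numeric(1)),
    N_pi1 = vapply(feats, function(f) as.numeric(f$N_pi1), numeric(1))
  )

  design_for <- function(exp_d, exp_a, F) {
    don <- vapply(feats, function(f) {
      if (nrow(f$donors)) sum(f$donors$sd * f$donors$n_H^exp_d) else 0
    }, numeric(1))
    acc <- vapply(feats, function(f) {
      if (nrow(f$acceptors)) {
        sum(f$acceptors$sa * f$acceptors$n_LP^exp_a)
      } else 0
    }, numeric(1))
    inter <- vapply(feats, function(f) {
      a <- f$acceptors$sa * f$acceptors$n_LP^exp_a
      near <- if (nrow(f$pairs_near)) {
        sum(a[f$pairs_near[, 1]] * a[f$pairs_near[, 2]])
      } else 0
      far <- if (nrow(f$pairs_nnn)) {
        sum(a[f$pairs_nnn[, 1]] * a[f$pairs_nnn[, 2]])
      } else 0
      2 * (near + F * far)
    }, numeric(1))
    cbind(dsum = don, asum = acc, const = base$const, N_s = base$N_s,
          N_r = base$N_r, N_pi2 = base$N_pi2, N_pi1 = base$N_pi1,
          isum = inter)
  }

  lin_names <- c("g_d", "g_a", "g_0", "g_s", "g_r", "g_pi2", "g_pi1", "g_i")

  mae_for <- function(p) {
    X <- design_for(p[["exp_d"]], p[["exp_a"]], p[["F"]])
    pred <- X %*% unlist(p[lin_names])
    mean(abs(pred - dg_exp))
  }

  solve_linear <- function(exp_d, exp_a, F, fallback) {
    X <- design_for(exp_d, exp_a, F)
    fit <- stats::lm.fit(X, dg_exp)
    co <- fit$coefficients
    co[is.na(co)] <- unlist(fallback[lin_names])[is.na(co)]
    co <- pmin(pmax(co, vapply(search_space[lin_names], `[[`, numeric(1), 1)),
               vapply(search_space[lin_names], `[[`, numeric(1), 2))
    as.list(stats::setNames(co, lin_names))
  }

  clamp <- function(v, nm) {
    min(max(v, search_space[[nm]][1]), search_space[[nm]][2])
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(seed)

  p0 <- params0[free_param_names()]
  best <- p0
  best_mae <- mae_for(p0)
  log_rows <- list(data.frame(trial = 1L, mae = best_mae,
                              as.data.frame(p0)))
  stall <- 0L
  trial <- 1L
  step <- 0.2
  nl_names <- c("exp_d", "exp_a", "F")
  while (trial < max_trials && stall < patience) {
    trial <- trial + 1L
    cand <- best
    if (stats::runif(1) < 0.1) {
      nm <- sample(nl_names, 1)
      cand[[nm]] <- stats::runif(1, search_space[[nm]][1],
                                 search_space[[nm]][2])
    } else {
      for (nm in nl_names) {
        cand[[nm]] <- clamp(cand[[nm]] * exp(stats::rnorm(1, 0, step)), nm)
      }
    }
    cand[lin_names] <- solve_linear(cand$exp_d, cand$exp_a, cand$F, best)
    mae <- mae_for(cand)
    log_rows[[length(log_rows) + 1]] <-
      data.frame(trial = trial, mae = mae, as.data.frame(cand))
    if (mae < best_mae) {
      best <- cand
      best_mae <- mae
      stall <- 0L
    } else {
      stall <- stall + 1L
      step <- max(step * 0.995, 1e-3)
    }
  }
  structure(list(
    best_params = set_free_params(params0, best),
    best_mae = best_mae,
    n_trials = trial,
    trial_log = do.call(rbind, log_rows),
    seed = seed
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %d trials, best MAE = %.4f kJ/mol (seed %d)\n",
              x$n_trials, x$best_mae, x$seed))
  print(x$best_params)
  invisible(x)
}
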