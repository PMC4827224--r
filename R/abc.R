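# ABC engine: reference table, rejection, logistic scenario choice,
# local-linear parameter adjustment, prior-error-rate validation.

.hash_text <- function(x) {
  f <- tempfile()
  writeLines(x, f)
  h <- unname(tools::md5sum(f))
  unlink(f)
  h
}

.scenario_set_hash <- function(scenario_set)
  .hash_text(paste(vapply(scenario_set, write_scenario, ""), collapse = "\n"))

.priors_hash <- function(priors)
  .hash_text(paste(utils::capture.output(print(as.data.frame(priors))),
                   collapse = "\n"))

#' Build an ABC reference table
#'
#' Simulates \code{n_sim} datasets with the scenario index drawn
#' uniformly over the set and parameters drawn from the priors, and
#' records scenario, parameter draw and summary-statistic vector per
#' simulation.  Work proceeds in chunks whose seeds derive from
#' \code{seed} by a counter scheme (\code{seed + chunk index}), so a
#' table is reproducible and, via \code{checkpoint_path}, resumable: on
#' resume the stored scenario-set/priors hashes must match (a mismatch
#' is a stale-table error) and completed chunks are reloaded.
#'
#' @param scenario_set named list of \code{Scenario}s.
#' @param priors a \code{PriorSpec} covering all scenario parameters.
#' @param design study design from \code{\link{make_design}}.
#' @param n_sim number of simulations.
#' @param seed base RNG seed.
#' @param chunk_size simulations per chunk.
#' @param checkpoint_path optional TSV path for checkpoint/resume.
#' @return An object of class \code{ReferenceTable}: \code{scenario}
#'   (character), \code{params} (data.frame, union of parameters, NA
#'   where a scenario lacks one), \code{stats} (matrix), \code{defined}
#'   (logical matrix), plus seed/hash metadata.
#' @export
build_reference_table <- function(scenario_set, priors,
                                  design = make_design(),
                                  n_sim = 30000L, seed = 1L,
                                  chunk_size = 1000L,
                                  checkpoint_path = NULL) {
  stopifnot(length(scenario_set) >= 1L, n_sim >= 1L)
  for (s in scenario_set) validate_scenario(s, priors)
  sc_hash <- .scenario_set_hash(scenario_set)
  pr_hash <- .priors_hash(priors)
  all_params <- unique(unlist(lapply(scenario_set, function(s)
    c(scenario_params(s), intersect(c("mu_seq", "kappa", "mu_msat", "p_geom"),
                                    priors$param)))))
  stat_names <- summary_vector_names(design$demes)

  n_chunks <- ceiling(n_sim / chunk_size)
  done <- 0L
  scen <- character(0); par_rows <- list(); stat_rows <- list(); def_rows <- list()

  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    hdr <- readLines(checkpoint_path, n = 1L)
    meta <- strsplit(sub("^#\\s*", "", hdr), "\t")[[1L]]
    if (length(meta) < 3L || meta[1L] != sc_hash || meta[2L] != pr_hash ||
        as.integer(meta[3L]) != as.integer(seed))
      stop("stale-table error: checkpoint was built from a different ",
           "scenario set, priors or seed")
    prev <- utils::read.table(checkpoint_path, header = TRUE, sep = "\t",
                              skip = 1L, stringsAsFactors = FALSE)
    done <- (nrow(prev) %/% chunk_size) * chunk_size  # only whole chunks
    if (done > 0L) {
      prev <- prev[seq_len(done), , drop = FALSE]
      scen <- prev$scenario
      par_rows <- list(prev[, all_params, drop = FALSE])
      stat_rows <- list(as.matrix(prev[, stat_names, drop = FALSE]))
      def_rows <- list(as.matrix(prev[, paste0("def_", stat_names),
                                      drop = FALSE]) > 0)
    }
  }
  if (!is.null(checkpoint_path) && !file.exists(checkpoint_path)) {
    writeLines(paste0("# ", sc_hash, "\t", pr_hash, "\t", seed),
               checkpoint_path)
    hdr_cols <- c("scenario", all_params, stat_names,
                  paste0("def_", stat_names))
    cat(paste(hdr_cols, collapse = "\t"), "\n", sep = "",
        file = checkpoint_path, append = TRUE)
  }

  names_set <- names(scenario_set)
  first_chunk <- done %/% chunk_size + 1L
  for (ch in seq_len(n_chunks)) {
    if (ch < first_chunk) next
    set.seed(as.integer(seed) + ch)
    n_here <- min(chunk_size, n_sim - (ch - 1L) * chunk_size)
    c_scen <- character(n_here)
    c_par <- matrix(NA_real_, n_here, length(all_params),
                    dimnames = list(NULL, all_params))
    c_stat <- matrix(NA_real_, n_here, length(stat_names),
                     dimnames = list(NULL, stat_names))
    c_def <- matrix(TRUE, n_here, length(stat_names))
    for (i in seq_len(n_here)) {
      sc <- names_set[sample.int(length(names_set), 1L)]
      s <- scenario_set[[sc]]
      draw <- sample_parameters(s, priors)
      sim <- simulate_dataset(s, draw, design)
      v <- summary_vector_sim(sim)
      c_scen[i] <- sc
      c_par[i, names(draw)] <- draw
      c_stat[i, ] <- v
      c_def[i, ] <- attr(v, "defined")
    }
    scen <- c(scen, c_scen)
    par_rows[[length(par_rows) + 1L]] <- as.data.frame(c_par)
    stat_rows[[length(stat_rows) + 1L]] <- c_stat
    def_rows[[length(def_rows) + 1L]] <- c_def
    if (!is.null(checkpoint_path)) {
      out <- data.frame(scenario = c_scen, c_par, c_stat,
                        0L + c_def, check.names = FALSE)
      utils::write.table(out, checkpoint_path, sep = "\t", append = TRUE,
                         col.names = FALSE, row.names = FALSE,
                         quote = FALSE)
    }
  }

  structure(list(scenario = scen,
                 params = do.call(rbind, par_rows),
                 stats = do.call(rbind, stat_rows),
                 defined = do.call(rbind, def_rows),
                 scenario_names = names_set,
                 scenario_hash = sc_hash, priors_hash = pr_hash,
                 seed = as.integer(seed), n_sim = as.integer(n_sim)),
            class = "ReferenceTable")
}

#' @export
print.ReferenceTable <- function(x, ...) {
  cat("ReferenceTable:", length(x$scenario), "simulations,",
      ncol(x$stats), "summary statistics; scenarios:",
      paste(x$scenario_names, collapse = ", "), "\n")
  invisible(x)
}

#' Rejection step: retain the simulations closest to the observed vector
#'
#' Each statistic channel is standardized by its median absolute
#' deviation over the table (falling back to the standard deviation for
#' channels where more than half the simulations tie, as happens with
#' mostly-monomorphic desk-scale tables); channels with no variation at
#' all, or undefined in the observed vector, are dropped.  Euclidean distance in the standardized
#' space ranks simulations; the \code{ceiling(tolerance * n)} closest
#' are retained (ties broken by simulation index).
#'
#' @param table a \code{ReferenceTable}.
#' @param observed a summary vector (\code{\link{summary_vector}}).
#' @param tolerance fraction retained, in (0, 1].
#' @param use_channels optional regular expression selecting channels
#'   (e.g. \code{"^mt_"} for an mtDNA-only analysis).
#' @return list of class \code{RejectionSample}: \code{index},
#'   \code{scenario}, \code{params}, \code{X} (standardized centered
#'   stats of retained rows), \code{distance}, \code{weight}
#'   (Epanechnikov), \code{channels}.
#' @export
rejection_sample <- function(table, observed, tolerance = 0.01,
                             use_channels = NULL) {
  stopifnot(inherits(table, "ReferenceTable"),
            tolerance > 0, tolerance <= 1)
  stats <- table$stats
  def_obs <- attr(observed, "defined")
  if (is.null(def_obs)) def_obs <- rep(TRUE, length(observed))
  # channels undefined for the observed data carry no signal; simulated
  # undefined entries stay as their 0 imputation (vector length fixed)
  keep <- def_obs
  if (!is.null(use_channels))
    keep <- keep & grepl(use_channels, colnames(stats))
  mads <- apply(stats, 2L, mad)
  sds <- apply(stats, 2L, sd)
  mads[mads == 0] <- sds[mads == 0]  # scale fallback when >50% of sims tie
  keep <- keep & mads > 0
  if (!any(keep)) stop("degenerate-statistics error: all channels dropped")
  ch <- which(keep)
  X <- sweep(sweep(stats[, ch, drop = FALSE], 2L, observed[ch], "-"),
             2L, mads[ch], "/")
  d <- sqrt(rowSums(X^2))
  n_ret <- ceiling(tolerance * nrow(stats))
  ord <- order(d, seq_along(d))[seq_len(n_ret)]
  dmax <- max(d[ord])
  w <- if (dmax > 0) 1 - (d[ord] / dmax)^2 else rep(1, n_ret)
  w[w <= 0] <- min(w[w > 0], 1e-8)  # keep boundary row usable
  list(index = ord, scenario = table$scenario[ord],
       params = table$params[ord, , drop = FALSE],
       X = X[ord, , drop = FALSE], distance = d[ord], weight = w,
       channels = colnames(stats)[ch])
}

#' Direct (rejection-proportion) scenario posterior estimate
#'
#' Proportion of retained simulations per scenario with Clopper-Pearson
#' 95\% confidence intervals.
#'
#' @param retained a \code{RejectionSample}.
#' @param scenario_names scenario labels (defaults to those present).
#' @return data.frame with columns \code{scenario}, \code{estimate},
#'   \code{lower}, \code{upper}, \code{n_retained}.
#' @export
model_choice_direct <- function(retained, scenario_names = NULL) {
  if (is.null(scenario_names)) scenario_names <- sort(unique(retained$scenario))
  n <- length(retained$scenario)
  k <- vapply(scenario_names, function(s) sum(retained$scenario == s), 0)
  lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
  hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
  data.frame(scenario = scenario_names, estimate = k / n,
             lower = lo, upper = hi, n_retained = n,
             stringsAsFactors = FALSE)
}

#' Logistic-regression scenario posterior estimate
#'
#' Weighted multinomial logistic regression of the scenario indicator on
#' the centered summary statistics over the retained simulations
#' (Epanechnikov weights in the rejection distance); the posterior
#' probabilities are the fitted class probabilities at the observed
#' point, with 95\% confidence intervals from the delta method on the
#' fitted coefficients' asymptotic covariance.  On separation or a
#' singular fit the regression is refit with a small ridge (weight
#' decay) penalty.  With fewer than two scenarios retained, or too few
#' rows, falls back to the direct estimate with a warning.
#'
#' @param retained a \code{RejectionSample}.
#' @param scenario_names scenario labels to report (defaults to those
#'   present in the retained set).
#' @param ridge ridge penalty used on fallback refit.
#' @return An object of class \code{ModelChoiceResult}: data.frame with
#'   \code{scenario}, \code{estimate} (logistic), \code{lower},
#'   \code{upper}, \code{direct}, \code{n_retained}; attributes
#'   \code{regularized} and \code{fallback}.
#' @export
model_choice_logistic <- function(retained, scenario_names = NULL,
                                  ridge = 1e-3) {
  direct <- model_choice_direct(retained, scenario_names)
  scenario_names <- direct$scenario
  present <- sort(unique(retained$scenario))
  n <- length(retained$scenario)
  p_dim <- ncol(retained$X)
  fallback <- FALSE
  if (length(present) < 2L || n < length(present) * (p_dim + 1L)) {
    warning("too few retained simulations for logistic regression; ",
            "falling back to the direct estimate")
    out <- direct
    names(out)[names(out) == "estimate"] <- "estimate"
    out$direct <- out$estimate
    attr(out, "fallback") <- TRUE
    attr(out, "regularized") <- FALSE
    class(out) <- c("ModelChoiceResult", "data.frame")
    return(out)
  }

  y <- factor(retained$scenario, levels = present)
  df <- data.frame(y = y, retained$X)
  xn <- colnames(retained$X)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", xn),
                                              collapse = " + ")))
  fit_once <- function(decay) {
    fit <- nnet::multinom(fml, data = df, weights = retained$weight,
                          trace = FALSE, maxit = 500L,
                          MaxNWts = 100000L, decay = decay)
    cf <- coef(fit)
    if (length(present) == 2L) cf <- matrix(cf, nrow = 1L,
                                            dimnames = list(present[2L],
                                                            names(cf)))
    V <- tryCatch(vcov(fit), error = function(e) NULL)
    list(fit = fit, cf = cf, V = V)
  }
  res <- tryCatch(fit_once(0), error = function(e) NULL)
  regularized <- FALSE
  bad <- is.null(res) || is.null(res$V) || any(!is.finite(res$V)) ||
    any(abs(res$cf[, "(Intercept)"]) > 30)
  if (bad) {
    res <- fit_once(ridge)
    regularized <- TRUE
  }

  # class probabilities at the observed point (X = 0): softmax of intercepts
  b0 <- res$cf[, "(Intercept)"]
  eta <- c(0, b0)
  pr <- exp(eta - max(eta)); pr <- pr / sum(pr)
  names(pr) <- present

  # delta method on the intercept block of vcov
  se <- rep(NA_real_, length(present))
  if (!is.null(res$V) && all(is.finite(res$V))) {
    vn <- colnames(res$V)
    if (is.null(vn)) vn <- rownames(res$V)
    int_idx <- grep("\\(Intercept\\)", vn)
    if (length(int_idx) == length(present) - 1L) {
      Vb <- res$V[int_idx, int_idx, drop = FALSE]
      for (j in seq_along(present)) {
        # d p_j / d b0_k = p_j (1[j==k] - p_k), k = 2..K
        g <- pr[j] * ((seq_along(present) == j) - pr)[-1L]
        se[j] <- sqrt(drop(t(g) %*% Vb %*% g))
      }
    }
  }
  est <- setNames(rep(0, length(scenario_names)), scenario_names)
  lo <- est; hi <- est
  est[present] <- pr
  lo[present] <- pmax(0, pr - 1.96 * ifelse(is.na(se), 0, se))
  hi[present] <- pmin(1, pr + 1.96 * ifelse(is.na(se), 0, se))
  absent <- setdiff(scenario_names, present)
  hi[absent] <- pmin(1, 3 / n)              # rule-of-three upper bound

  out <- data.frame(scenario = scenario_names, estimate = unname(est),
                    lower = unname(lo), upper = unname(hi),
                    direct = direct$estimate[match(scenario_names,
                                                   direct$scenario)],
                    n_retained = n, stringsAsFactors = FALSE)
  attr(out, "regularized") <- regularized
  attr(out, "fallback") <- fallback
  class(out) <- c("ModelChoiceResult", "data.frame")
  out
}

#' @export
print.ModelChoiceResult <- function(x, ...) {
  cat("Scenario choice (", x$n_retained[1L], " retained)\n", sep = "")
  print(data.frame(scenario = x$scenario,
                   logistic = round(x$estimate, 4),
                   ci = sprintf("[%.4f, %.4f]", x$lower, x$upper),
                   direct = round(x$direct, 4)), row.names = FALSE)
  invisible(x)
}

# weighted quantiles (type-4-style interpolation on the weighted ecdf)
.wquantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1L]
    if (is.na(i)) x[length(x)] else x[i]
  }, 0)
}

#' Local-linear parameter estimation from retained simulations
#'
#' Beaumont-style adjustment: each parameter (logit-transformed to its
#' prior support; log scale first for log-uniform priors) is regressed
#' on the centered standardized statistics with Epanechnikov weights,
#' draws are corrected to the observed point
#' (\eqn{\theta^* = \theta - X \hat\beta}), back-transformed, and
#' summarized.  A singular regression falls back to the unadjusted
#' draws with a warning.
#'
#' @param retained a \code{RejectionSample} restricted to one scenario
#'   (see \code{\link{rejection_sample}}; subset by scenario first).
#' @param priors the \code{PriorSpec} (for transform bounds).
#' @param params parameters to estimate (default: all with data).
#' @return data.frame of class \code{ParamEstimate}: per parameter the
#'   posterior mean, median, mode, and 2.5\%/97.5\% quantiles of the
#'   adjusted draws, plus an \code{adjusted} flag.
#' @export
estimate_parameters_loclinear <- function(retained, priors, params = NULL) {
  P <- retained$params
  if (is.null(params))
    params <- colnames(P)[colSums(!is.na(P)) > 0]
  X <- retained$X
  w <- retained$weight
  n <- nrow(X)
  if (n < ncol(X) + 2L)
    stop("need at least (number of statistics + 2) retained rows")
  out <- lapply(params, function(pm) {
    theta <- P[[pm]]
    ok <- !is.na(theta)
    pr <- priors[priors$param == pm, ]
    if (nrow(pr) != 1L) stop("no prior for parameter ", pm)
    loglink <- pr$dist == "loguniform"
    lo <- if (loglink) log(pr$lo) else pr$lo
    hi <- if (loglink) log(pr$hi) else pr$hi
    th <- if (loglink) log(theta[ok]) else theta[ok]
    u <- pmin(pmax((th - lo) / (hi - lo), 1e-9), 1 - 1e-9)
    z <- log(u / (1 - u))
    Xo <- X[ok, , drop = FALSE]
    fit <- tryCatch(stats::lm.wfit(cbind(1, Xo), z, w[ok]),
                    error = function(e) NULL)
    adjusted <- TRUE
    if (is.null(fit) || any(!is.finite(stats::coef(fit)))) {
      beta <- rep(0, ncol(Xo))
      warning("singular local-linear regression for ", pm,
              "; using unadjusted draws")
      adjusted <- FALSE
    } else {
      beta <- stats::coef(fit)[-1L]
      beta[is.na(beta)] <- 0
    }
    zstar <- z - drop(Xo %*% beta)
    ustar <- 1 / (1 + exp(-zstar))
    thstar <- lo + ustar * (hi - lo)
    if (loglink) thstar <- exp(thstar)
    ww <- w[ok]
    q <- .wquantile(thstar, ww, c(0.025, 0.5, 0.975))
    dens <- tryCatch(suppressWarnings(
      stats::density(thstar, weights = ww / sum(ww))),
      error = function(e) NULL)
    mode <- if (is.null(dens)) q[2L] else dens$x[which.max(dens$y)]
    data.frame(param = pm,
               mean = sum(ww * thstar) / sum(ww),
               median = q[2L], mode = mode,
               q025 = q[1L], q975 = q[3L],
               adjusted = adjusted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("ParamEstimate", "data.frame")
  out
}

#' Prior error rate of scenario choice over pseudo-observed datasets
#'
#' Analyzes each POD with rejection plus logistic model choice against
#' the supplied reference table, takes the argmax posterior as the
#' chosen scenario, and tallies the confusion matrix.  PODs must be
#' generated with a seed disjoint from the table's seed stream.
#'
#' @param pods a \code{PodSet} from \code{\link{generate_pod}}.
#' @param table a \code{ReferenceTable}.
#' @param tolerance rejection tolerance.
#' @param use_channels optional channel regexp (see
#'   \code{\link{rejection_sample}}).
#' @return list of class \code{ConfusionMatrix}: \code{matrix}
#'   (true x chosen counts), \code{error_rate}, \code{chosen},
#'   \code{posteriors} (per-POD logistic estimates).
#' @export
prior_error_rate <- function(pods, table, tolerance = 0.01,
                             use_channels = NULL) {
  scen <- table$scenario_names
  cm <- matrix(0L, length(scen), length(scen), dimnames = list(scen, scen))
  chosen <- character(length(pods))
  post <- matrix(NA_real_, length(pods), length(scen),
                 dimnames = list(NULL, scen))
  for (i in seq_along(pods)) {
    rej <- rejection_sample(table, pods[[i]]$stats, tolerance, use_channels)
    mc <- suppressWarnings(model_choice_logistic(rej, scenario_names = scen))
    k <- mc$scenario[which.max(mc$estimate)]
    chosen[i] <- k
    post[i, mc$scenario] <- mc$estimate
    cm[pods[[i]]$scenario, k] <- cm[pods[[i]]$scenario, k] + 1L
  }
  truth <- vapply(pods, `[[`, "", "scenario")
  structure(list(matrix = cm, error_rate = mean(chosen != truth),
                 chosen = chosen, truth = truth, posteriors = post),
            class = "ConfusionMatrix")
}

#' @export
print.ConfusionMatrix <- function(x, ...) {
  cat("Scenario-recovery confusion matrix (rows = truth):\n")
  print(x$matrix)
  cat(sprintf("prior error rate = %.3f\n", x$error_rate))
  invisible(x)
}
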