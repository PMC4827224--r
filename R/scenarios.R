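# Declarative demographic scenarios: demes, timed events (backward in
# time), and parameter priors.  Events reference named parameters (t1,
# r1, N_ZF, ...) that are drawn from a PriorSpec at simulation time.

#' Construct a demographic scenario
#'
#' A scenario is a set of demes plus an ordered, backward-in-time event
#' list.  Event kinds: \code{split} (all lineages of \code{source} merge
#' into \code{dest} at its time), \code{admix} (each lineage of
#' \code{source} goes to \code{parent1} with probability r, else
#' \code{parent2}; the source deme then ceases to exist), and
#' \code{resize} (the deme's size parameter changes).
#'
#' @param name scenario name.
#' @param demes data.frame with columns \code{name}, \code{sampled}
#'   (logical), \code{size_param}.
#' @param events list of event lists, each with fields \code{kind},
#'   \code{time} (parameter name), and kind-specific fields
#'   (\code{source}, \code{dest}, \code{parent1}, \code{parent2},
#'   \code{r}, \code{size}).
#' @param time_order character vector of time-parameter names that must
#'   be strictly increasing.
#' @param assumption logical flag: the topology is an interpretation
#'   rather than a directly stated history.
#' @return An object of class \code{Scenario}.
#' @export
scenario <- function(name, demes, events, time_order = character(0),
                     assumption = FALSE) {
  stopifnot(all(c("name", "sampled", "size_param") %in% names(demes)))
  structure(list(name = name, demes = demes, events = events,
                 time_order = time_order, assumption = assumption),
            class = "Scenario")
}

#' @export
print.Scenario <- function(x, ...) {
  cat("Scenario", x$name, "-", nrow(x$demes), "demes,",
      length(x$events), "events",
      if (isTRUE(x$assumption)) "(topology flagged as assumption)" else "",
      "\n")
  invisible(x)
}

# all parameter names a scenario references
scenario_params <- function(s) {
  times <- vapply(s$events, `[[`, "", "time")
  rs <- unlist(lapply(s$events, function(e) e$r))
  sizes <- c(s$demes$size_param,
             unlist(lapply(s$events, function(e) e$size)))
  unique(c(sizes, times, rs))
}

#' Validate a scenario's structure
#'
#' Checks that every deme's lineage path reaches a single root deme,
#' that no event references a deme after it has merged away
#' (live-interval consistency), that admixture proportions have priors
#' inside (0, 1), and that the time-order constraints are satisfiable.
#'
#' @param s a \code{Scenario}.
#' @param priors optional \code{\link{default_priors}}-style data.frame;
#'   if given, r bounds and prior coverage are also checked.
#' @return invisibly \code{TRUE}; otherwise an error describing the
#'   defect.
#' @export
validate_scenario <- function(s, priors = NULL) {
  demes <- s$demes$name
  if (anyDuplicated(demes)) stop("duplicate deme names")
  # satisfiability of time order: parameter names must be unique chain
  if (anyDuplicated(s$time_order))
    stop("constraint error: cyclic/duplicated time-order constraints")
  # events are listed in schedule order; walk liveness
  alive <- setNames(rep(TRUE, length(demes)), demes)
  n_alive_end <- length(demes)
  for (e in s$events) {
    if (e$kind == "split") {
      if (!alive[e$source])
        stop("live-interval error: split source '", e$source,
             "' already merged away")
      if (!alive[e$dest])
        stop("live-interval error: split destination '", e$dest,
             "' already merged away")
      alive[e$source] <- FALSE
      n_alive_end <- n_alive_end - 1L
    } else if (e$kind == "admix") {
      if (!alive[e$source])
        stop("live-interval error: admixture target '", e$source,
             "' already merged away")
      if (!alive[e$parent1] || !alive[e$parent2])
        stop("live-interval error: admixture parent not alive")
      alive[e$source] <- FALSE
      n_alive_end <- n_alive_end - 1L
    } else if (e$kind == "resize") {
      if (!alive[e$deme])
        stop("live-interval error: resizing a merged deme")
    } else stop("unknown event kind: ", e$kind)
  }
  if (n_alive_end != 1L)
    stop("structural error: ", n_alive_end,
         " demes never coalesce into a single root")
  if (!is.null(priors)) {
    need <- scenario_params(s)
    missing <- setdiff(need, priors$param)
    if (length(missing))
      stop("priors missing for parameters: ", paste(missing, collapse = ", "))
    for (e in s$events) if (e$kind == "admix") {
      pr <- priors[priors$param == e$r, ]
      if (pr$lo <= 0 || pr$hi >= 1)
        stop("admixture proportion prior for ", e$r, " must lie in (0, 1)")
    }
  }
  invisible(TRUE)
}

#' Preset scenarios A-E for the four-deme study design
#'
#' The study's eight populations pool into four demes: ZF
#' (Zhejiang-Fujian: JO, HA), PR (Pearl River: HY, JX, CX), NH (northern
#' Hainan: QH, BS) and SH (southern Hainan: LD).  Backward in time:
#' \describe{
#'   \item{A (null)}{all four demes merge into a common ancestor at t1.}
#'   \item{B (mtDNA phylogenetic)}{PR is admixed from NH (prob r1) and
#'     ZF at t1; ZF merges into NH at t2; NH merges into the SH ancestor
#'     at t3 (t1 < t2 < t3).}
#'   \item{C (mtDNA dispersal-vicariance)}{PR is admixed from NH and an
#'     unsampled pre-admixture coastal lineage C0 at t1; ZF merges into
#'     C0 at t2; C0 merges into NH at t3; NH merges into the SH ancestor
#'     at t4 (t1 < t2 < t3 < t4).}
#'   \item{D (microsatellite phylogenetic)}{divergence-only
#'     ((PR,NH),(ZF,SH)): within-group splits at a shared recent time,
#'     root split later.  Topology flagged as an assumption.}
#'   \item{E (microsatellite clustering)}{four-deme divergence with PR
#'     admixed from ZF and NH.  Topology flagged as an assumption.}
#' }
#'
#' @param design a study design from \code{\link{make_design}} (used only
#'   to check the expected demes are present).
#' @return named list of \code{Scenario} objects A-E.
#' @export
preset_scenarios <- function(design = make_design()) {
  need <- c("ZF", "PR", "NH", "SH")
  if (!all(need %in% design$demes))
    stop("design must contain demes ", paste(need, collapse = ", "))
  d4 <- data.frame(name = need, sampled = TRUE,
                   size_param = paste0("N_", need), stringsAsFactors = FALSE)
  with_anc <- rbind(d4, data.frame(name = "ANC", sampled = FALSE,
                                   size_param = "N_A"))
  with_c0 <- rbind(d4, data.frame(name = "C0", sampled = FALSE,
                                  size_param = "N_C0"))
  A <- scenario("A", with_anc, list(
    list(kind = "split", time = "t1", source = "ZF", dest = "ANC"),
    list(kind = "split", time = "t1", source = "PR", dest = "ANC"),
    list(kind = "split", time = "t1", source = "NH", dest = "ANC"),
    list(kind = "split", time = "t1", source = "SH", dest = "ANC")),
    time_order = "t1")
  B <- scenario("B", d4, list(
    list(kind = "admix", time = "t1", source = "PR",
         parent1 = "NH", parent2 = "ZF", r = "r1"),
    list(kind = "split", time = "t2", source = "ZF", dest = "NH"),
    list(kind = "split", time = "t3", source = "NH", dest = "SH")),
    time_order = c("t1", "t2", "t3"))
  C <- scenario("C", with_c0, list(
    list(kind = "admix", time = "t1", source = "PR",
         parent1 = "NH", parent2 = "C0", r = "r1"),
    list(kind = "split", time = "t2", source = "ZF", dest = "C0"),
    list(kind = "split", time = "t3", source = "C0", dest = "NH"),
    list(kind = "split", time = "t4", source = "NH", dest = "SH")),
    time_order = c("t1", "t2", "t3", "t4"))
  D <- scenario("D", d4, list(
    list(kind = "split", time = "t1", source = "PR", dest = "NH"),
    list(kind = "split", time = "t1", source = "ZF", dest = "SH"),
    list(kind = "split", time = "t2", source = "NH", dest = "SH")),
    time_order = c("t1", "t2"), assumption = TRUE)
  E <- scenario("E", d4, list(
    list(kind = "admix", time = "t1", source = "PR",
         parent1 = "ZF", parent2 = "NH", r = "r1"),
    list(kind = "split", time = "t2", source = "ZF", dest = "SH"),
    list(kind = "split", time = "t2", source = "NH", dest = "SH")),
    time_order = c("t1", "t2"), assumption = TRUE)
  list(A = A, B = B, C = C, D = D, E = E)
}

#' Default parameter priors
#'
#' Uniform/log-uniform priors over every parameter the preset scenarios
#' and mutation models reference.  Effective sizes N are diploid; times
#' are in generations; mutation rates are per site (sequence) or per
#' locus (microsatellite) per generation.
#'
#' @param params optional character vector restricting to the named
#'   parameters.
#' @return data.frame of class \code{PriorSpec} with columns
#'   \code{param}, \code{dist} (\code{uniform}/\code{loguniform}),
#'   \code{lo}, \code{hi}.
#' @export
default_priors <- function(params = NULL) {
  base <- rbind(
    data.frame(param = c("N_ZF", "N_PR", "N_NH", "N_SH", "N_A", "N_C0"),
               dist = "loguniform", lo = 1e2, hi = 1e5),
    data.frame(param = c("t1", "t2", "t3", "t4"),
               dist = "uniform", lo = 10, hi = 1e5),
    data.frame(param = "r1", dist = "uniform", lo = 0.05, hi = 0.95),
    data.frame(param = "mu_seq", dist = "loguniform", lo = 1e-9, hi = 1e-7),
    data.frame(param = "kappa", dist = "uniform", lo = 2, hi = 20),
    data.frame(param = "mu_msat", dist = "loguniform", lo = 1e-5, hi = 1e-3),
    data.frame(param = "p_geom", dist = "uniform", lo = 0, hi = 0.3))
  if (!is.null(params)) {
    missing <- setdiff(params, base$param)
    if (length(missing))
      stop("no default prior for: ", paste(missing, collapse = ", "))
    base <- base[base$param %in% params, ]
  }
  rownames(base) <- NULL
  class(base) <- c("PriorSpec", "data.frame")
  base
}

#' Draw one parameter set from priors
#'
#' Samples every parameter the scenario references (plus the mutation
#' hyperparameters if present in the priors), then rejection-resamples
#' until the scenario's time-order constraints hold.
#'
#' @param s a \code{Scenario}.
#' @param priors a \code{PriorSpec}.
#' @param max_tries rejection cap; exceeding it (acceptance below about
#'   1e-4) signals inconsistent priors.
#' @return named numeric vector of parameter values.
#' @export
sample_parameters <- function(s, priors, max_tries = 10000L) {
  need <- unique(c(scenario_params(s),
                   intersect(c("mu_seq", "kappa", "mu_msat", "p_geom"),
                             priors$param)))
  pr <- priors[match(need, priors$param), ]
  if (anyNA(pr$param))
    stop("priors missing for: ",
         paste(need[is.na(pr$param)], collapse = ", "))
  is_log <- pr$dist == "loguniform"
  draw1 <- function() {
    v <- runif(nrow(pr), pr$lo, pr$hi)
    if (any(is_log))
      v[is_log] <- exp(runif(sum(is_log), log(pr$lo[is_log]),
                             log(pr$hi[is_log])))
    setNames(v, pr$param)
  }
  ord <- intersect(s$time_order, need)
  for (i in seq_len(max_tries)) {
    v <- draw1()
    if (length(ord) < 2L || all(diff(v[ord]) > 0)) return(v)
  }
  stop("prior-inconsistency error: time-order constraints accepted fewer ",
       "than 1 in ", max_tries, " draws")
}

#' Serialize scenarios and priors to the line-oriented text format
#'
#' One event per line (\code{split t2 ZF C0}, \code{admix t1 PR NH C0 r1},
#' \code{resize t3 NH N5}); deme declarations as \code{deme ZF sampled
#' N_ZF}; priors as \code{prior t1 uniform 10 1e+05}.
#'
#' @param s a \code{Scenario}.
#' @param priors optional \code{PriorSpec} appended as \code{prior} lines.
#' @return a single string.
#' @export
write_scenario <- function(s, priors = NULL) {
  lines <- c(paste("scenario", s$name,
                   if (isTRUE(s$assumption)) "assumption" else ""),
             vapply(seq_len(nrow(s$demes)), function(i)
               paste("deme", s$demes$name[i],
                     if (s$demes$sampled[i]) "sampled" else "unsampled",
                     s$demes$size_param[i]), ""))
  for (e in s$events) {
    lines <- c(lines, switch(e$kind,
      split = paste("split", e$time, e$source, e$dest),
      admix = paste("admix", e$time, e$source, e$parent1, e$parent2, e$r),
      resize = paste("resize", e$time, e$deme, e$size)))
  }
  if (length(s$time_order))
    lines <- c(lines, paste("order", paste(s$time_order, collapse = " ")))
  if (!is.null(priors))
    lines <- c(lines, vapply(seq_len(nrow(priors)), function(i)
      paste("prior", priors$param[i], priors$dist[i],
            format(priors$lo[i]), format(priors$hi[i])), ""))
  paste0(paste(trimws(lines), collapse = "\n"), "\n")
}

#' Parse the line-oriented scenario format
#'
#' @param text string, character vector of lines, or file path.
#' @return list with elements \code{scenario} and (if prior lines are
#'   present) \code{priors}.
#' @export
read_scenario <- function(text) {
  lines <- .as_lines(text)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  toks <- strsplit(lines, "\\s+")
  name <- "unnamed"; assumption <- FALSE
  demes <- list(); events <- list(); time_order <- character(0)
  priors <- list()
  for (tk in toks) {
    switch(tk[1L],
      scenario = { name <- tk[2L]
                   assumption <- length(tk) > 2L && tk[3L] == "assumption" },
      deme = demes[[length(demes) + 1L]] <-
        data.frame(name = tk[2L], sampled = tk[3L] == "sampled",
                   size_param = tk[4L], stringsAsFactors = FALSE),
      split = events[[length(events) + 1L]] <-
        list(kind = "split", time = tk[2L], source = tk[3L], dest = tk[4L]),
      admix = events[[length(events) + 1L]] <-
        list(kind = "admix", time = tk[2L], source = tk[3L],
             parent1 = tk[4L], parent2 = tk[5L], r = tk[6L]),
      resize = events[[length(events) + 1L]] <-
        list(kind = "resize", time = tk[2L], deme = tk[3L], size = tk[4L]),
      order = time_order <- tk[-1L],
      prior = priors[[length(priors) + 1L]] <-
        data.frame(param = tk[2L], dist = tk[3L],
                   lo = as.numeric(tk[4L]), hi = as.numeric(tk[5L]),
                   stringsAsFactors = FALSE),
      stop("unknown scenario-file directive: ", tk[1L]))
  }
  s <- scenario(name, do.call(rbind, demes), events, time_order, assumption)
  out <- list(scenario = s)
  if (length(priors)) {
    pr <- do.call(rbind, priors)
    class(pr) <- c("PriorSpec", "data.frame")
    out$priors <- pr
  }
  out
}
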