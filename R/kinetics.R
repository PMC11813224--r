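## Branched sequential-cleavage kinetic model in the linear regime.
##
## At saturating substrate (5 uM C99 vs 30 nM enzyme) product formation
## is linear in time: N = kcat * [E] * t total turnovers (in nM).  Each
## turnover commits to the Abeta49 branch with probability p49, then at
## every trimming step either continues (probability q) or releases the
## intermediate.  Released intermediates do not re-bind, so measured
## per-step efficiencies identify q directly.

#' Kinetic parameters for the processive-proteolysis simulator
#'
#' @param kcat Turnover number (hr^-1); wild-type enzyme ~2 hr^-1.
#' @param enzyme_conc Enzyme concentration (nM); assay default 30 nM.
#' @param time Incubation time (hr); assay default 16 hr (still within
#'   the linear range at these rates).
#' @param branch_p49 Probability that endoproteolysis takes the Abeta49
#'   (Abeta40-bound) branch; the Abeta48 branch gets `1 - branch_p49`.
#' @param continue_prob Named numeric in `[0, 1]` over the six trimming
#'   step ids (`"Ab49->Ab46"`, ..., `"Ab42->Ab38"`): probability that a
#'   bound intermediate is trimmed rather than released.
#' @param rate_pairs Optional named list over step ids of
#'   `c(k_cleave, k_release)` (hr^-1).  When both `rate_pairs` and
#'   `continue_prob` are given, `k_cleave / (k_cleave + k_release)` must
#'   equal the step's `continue_prob`.
#' @param noise_cv Coefficient of variation of multiplicative
#'   measurement noise (>= 0).
#' @param noise_model `"lognormal"` (mean-one multiplicative, the
#'   default for scale-proportional MS responses) or `"gaussian"`.
#' @param n_replicates Number of replicates to simulate (default 4).
#' @param detection_floor Named numeric of per-coproduct detection
#'   floors (nM); simulated values below a coproduct's floor are
#'   censored.  Default: 62.5 nM for the two AICDs (the lowest AICD
#'   standard), no floor for the small peptides.
#' @param seed Integer seed for reproducible simulation (no global RNG
#'   state is touched).
#' @return A validated object of class `kinetic_params`.
#' @export
kinetic_params <- function(kcat = 2, enzyme_conc = 30, time = 16,
                           branch_p49 = 0.5,
                           continue_prob = c(
                             "Ab49->Ab46" = 0.9, "Ab46->Ab43" = 0.6,
                             "Ab43->Ab40" = 0.66, "Ab48->Ab45" = 0.76,
                             "Ab45->Ab42" = 0.63, "Ab42->Ab38" = 0.13),
                           rate_pairs = NULL,
                           noise_cv = 0.1, noise_model = c("lognormal", "gaussian"),
                           n_replicates = 4L,
                           detection_floor = c("AICD50-99" = 62.5,
                                               "AICD49-99" = 62.5),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  # configs (YAML/JSON) deliver named lists; accept them
  if (is.list(continue_prob)) continue_prob <- unlist(continue_prob)
  if (is.list(detection_floor)) detection_floor <- unlist(detection_floor)
  stopifnot(is.numeric(kcat), kcat >= 0,
            is.numeric(enzyme_conc), enzyme_conc >= 0,
            is.numeric(time), time >= 0)
  if (!is.numeric(branch_p49) || branch_p49 < 0 || branch_p49 > 1) {
    stop("`branch_p49` must be a probability in [0, 1]", call. = FALSE)
  }
  if (any(!is.finite(continue_prob)) || any(continue_prob < 0) ||
      any(continue_prob > 1)) {
    stop("`continue_prob` entries must be probabilities in [0, 1]",
         call. = FALSE)
  }
  if (is.null(names(continue_prob))) {
    stop("`continue_prob` must be named by step id", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be >= 0", call. = FALSE)
  }
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L) {
    stop("`n_replicates` must be an integer >= 1", call. = FALSE)
  }
  if (!is.null(rate_pairs)) {
    for (id in names(rate_pairs)) {
      rp <- rate_pairs[[id]]
      if (length(rp) != 2L || any(!is.finite(rp)) || any(rp < 0)) {
        stop("rate pair for ", id, " must be two non-negative rates",
             call. = FALSE)
      }
      if (id %in% names(continue_prob) && sum(rp) > 0) {
        q_rate <- rp[[1]] / sum(rp)
        if (abs(q_rate - continue_prob[[id]]) > 1e-8) {
          stop("rate pair for ", id, " implies q = ", signif(q_rate, 6),
               " but continue_prob is ", continue_prob[[id]], call. = FALSE)
        }
      }
    }
  }
  structure(
    list(kcat = kcat, enzyme_conc = enzyme_conc, time = time,
         branch_p49 = branch_p49, continue_prob = continue_prob,
         rate_pairs = rate_pairs, noise_cv = noise_cv,
         noise_model = noise_model, n_replicates = n_replicates,
         detection_floor = detection_floor, seed = as.integer(seed)),
    class = "kinetic_params"
  )
}

# Run `expr` under a private RNG stream; the caller's global RNG state
# is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

branch_probability <- function(params, first_product) {
  if (identical(first_product, "Ab49")) params$branch_p49 else 1 - params$branch_p49
}

expected_coproduct_values <- function(params, graph) {
  st <- graph_steps(graph)
  total <- params$kcat * params$enzyme_conc * params$time
  out <- stats::setNames(numeric(nrow(st)), st$coproduct)
  for (b in unique(st$branch)) {
    sb <- st[st$branch == b, ]
    p <- branch_probability(params, sb$product[1])
    flux <- total * p
    for (i in seq_len(nrow(sb))) {
      if (i > 1L) {
        q <- params$continue_prob[[sb$step[i]]]
        if (is.null(q)) stop("no continue_prob for step ", sb$step[i],
                             call. = FALSE)
        flux <- flux * q
      }
      out[sb$coproduct[i]] <- flux
    }
  }
  out
}

#' Expected (noiseless) coproducts and pools
#'
#' Closed form of the linear-regime model: total turnovers
#' `N = kcat * enzyme_conc * time` (nM); the endoproteolysis coproduct
#' of a branch is `N * p_branch` and the coproduct of trimming step i is
#' `N * p_branch * prod(q)` over steps up to i.  Pools follow by mass
#' balance (production minus consumption), so running
#' [pools_from_coproducts()] on the returned coproducts reproduces the
#' returned pool table exactly, and [step_efficiencies()] returns
#' exactly `100 * q`.
#'
#' @param params A [kinetic_params()].
#' @param graph A `pathway_graph`.
#' @param variant Label attached to the output tables.
#' @param channel Isotope channel label.
#' @return List with elements `coproducts` (a `coproduct_table`) and
#'   `pools` (a `pool_table`).
#' @examples
#' p <- kinetic_params(kcat = 2, enzyme_conc = 30, time = 16,
#'                     branch_p49 = 0.5,
#'                     continue_prob = c("Ab49->Ab46" = 0.9,
#'                                       "Ab46->Ab43" = 0.6,
#'                                       "Ab43->Ab40" = 0.7,
#'                                       "Ab48->Ab45" = 0.76,
#'                                       "Ab45->Ab42" = 0.63,
#'                                       "Ab42->Ab38" = 0.13))
#' ep <- expected_products(p)
#' ep$coproducts$values[["AICD50-99"]]  # 480
#' ep$pools$pools[["Ab46"]]             # 172.8
#' @export
expected_products <- function(params, graph = default_pathway(),
                              variant = "simulated", channel = "light") {
  stopifnot(inherits(params, "kinetic_params"))
  vals <- expected_coproduct_values(params, graph)
  cpt <- coproduct_table(vals, variant = variant, channel = channel,
                         graph = graph)
  list(coproducts = cpt, pools = pools_from_coproducts(cpt, graph))
}

apply_noise <- function(values, cv, model, n) {
  if (cv == 0) return(values)
  if (model == "lognormal") {
    sdlog <- sqrt(log1p(cv^2))
    fac <- stats::rlnorm(length(values), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    fac <- pmax(0, stats::rnorm(length(values), mean = 1, sd = cv))
  }
  values * fac
}

censor_floor <- function(values, floor) {
  out <- as.list(values)
  if (length(floor)) {
    for (id in intersect(names(floor), names(values))) {
      if (!is.na(values[[id]]) && values[[id]] < floor[[id]]) {
        out[[id]] <- censored(floor[[id]])
      }
    }
  }
  out
}

stochastic_coproduct_values <- function(params, graph) {
  st <- graph_steps(graph)
  total <- params$kcat * params$enzyme_conc * params$time
  n_total <- stats::rpois(1L, total)
  out <- stats::setNames(numeric(nrow(st)), st$coproduct)
  branches <- unique(st$branch)
  first <- st[st$index == 1L, ]
  p49 <- branch_probability(params, "Ab49")
  # route each turnover: branch choice, then survival down the chain
  n49 <- stats::rbinom(1L, n_total, p49)
  counts <- stats::setNames(c(n49, n_total - n49), c("Ab49", "Ab48"))
  for (b in branches) {
    sb <- st[st$branch == b, ]
    n <- counts[[sb$product[1]]]
    out[sb$coproduct[1]] <- n
    for (i in seq_len(nrow(sb))[-1]) {
      n <- stats::rbinom(1L, n, params$continue_prob[[sb$step[i]]])
      out[sb$coproduct[i]] <- n
    }
  }
  out
}

#' Simulate replicate coproduct tables
#'
#' Generates `params$n_replicates` independent coproduct tables.  In
#' the default expectation mode each replicate is the closed-form
#' expectation times independent multiplicative noise (mean-one
#' lognormal with CV `noise_cv`, or truncated Gaussian).  In
#' `mode = "stochastic"` the turnover count is drawn as
#' Poisson(kcat*E*t) and every turnover is routed through the branch
#' and continuation choices as Bernoulli draws (one turnover = 1 nM),
#' before the same measurement noise is applied.  Values below a
#' coproduct's detection floor are emitted as [censored()].
#' Reproducible given `params$seed`; the global RNG state is untouched.
#'
#' @param params A [kinetic_params()].
#' @param graph A `pathway_graph`.
#' @param variant Label for the simulated variant.
#' @param channel Isotope channel label.
#' @param mode `"expectation"` (default) or `"stochastic"`.
#' @return List of `coproduct_table`s, one per replicate.
#' @export
simulate_replicates <- function(params, graph = default_pathway(),
                                variant = "simulated", channel = "light",
                                mode = c("expectation", "stochastic")) {
  stopifnot(inherits(params, "kinetic_params"))
  mode <- match.arg(mode)
  expect <- expected_coproduct_values(params, graph)
  with_seed(params$seed, {
    lapply(seq_len(params$n_replicates), function(r) {
      base <- if (mode == "stochastic") {
        stochastic_coproduct_values(params, graph)
      } else {
        expect
      }
      noisy <- apply_noise(base, params$noise_cv, params$noise_model,
                           length(base))
      vals <- censor_floor(noisy, params$detection_floor)
      coproduct_table(vals, variant = variant, replicate = r,
                      channel = channel, graph = graph)
    })
  })
}

#' Occupancy profile of enzyme-intermediate complexes
#'
#' Embodies the stalled-complex picture quantitatively.  The states are
#' the branch-committed enzyme-intermediate complexes (E.Abeta49,
#' E.Abeta46, E.Abeta43; E.Abeta48, E.Abeta45, E.Abeta42); each state's
#' single outgoing trimming step has a rate pair `(k_cleave,
#' k_release)` with continuation probability `q = k_cleave / (k_cleave +
#' k_release)`.  Then
#' \itemize{
#'   \item visit probability = branch probability x product of upstream q,
#'   \item mean residence = `1 / (k_cleave + k_release)` (hr),
#'   \item occupancy fraction = visit x residence, normalised to sum to
#'     one over visited states.
#' }
#' Scaling a state's two rates down at fixed q leaves every visit
#' probability unchanged but lengthens that state's residence, so its
#' occupancy fraction strictly increases: a slow step stalls the enzyme
#' on its intermediate.
#'
#' @param params A [kinetic_params()] whose `rate_pairs` cover every
#'   step reachable with positive probability.
#' @param graph A `pathway_graph`.
#' @return Data.frame with one row per visited state: `state` (bound
#'   species), `step` (outgoing step id), `visit_probability`,
#'   `mean_residence` (hr), `occupancy_fraction`.
#' @export
occupancy_profile <- function(params, graph = default_pathway()) {
  stopifnot(inherits(params, "kinetic_params"))
  if (is.null(params$rate_pairs)) {
    stop("`params$rate_pairs` are required for an occupancy profile",
         call. = FALSE)
  }
  st <- graph_steps(graph)
  trims <- st[st$index > 1L, ]
  rows <- list()
  for (b in unique(trims$branch)) {
    sb <- st[st$branch == b, ]
    p <- branch_probability(params, sb$product[1])
    visit <- p
    for (i in seq_len(nrow(sb))[-1]) {
      id <- sb$step[i]
      state <- sb$precursor[i]   # the bound intermediate
      if (visit > 0) {
        rp <- params$rate_pairs[[id]]
        if (is.null(rp)) {
          stop("no rate pair for visited step ", id, call. = FALSE)
        }
        if (sum(rp) <= 0) {
          stop("zero total rate at visited state ", state, call. = FALSE)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          state = state, step = id, visit_probability = visit,
          mean_residence = 1 / sum(rp), stringsAsFactors = FALSE)
      }
      q <- params$continue_prob[[id]]
      if (is.null(q)) {
        rp <- params$rate_pairs[[id]]
        q <- rp[[1]] / sum(rp)
      }
      visit <- visit * q
    }
  }
  if (!length(rows)) stop("no state is visited with positive probability",
                          call. = FALSE)
  out <- do.call(rbind, rows)
  w <- out$visit_probability * out$mean_residence
  out$occupancy_fraction <- w / sum(w)
  out
}

#' Recover the turnover number from a linear time course
#'
#' In the linear regime total endoproteolysis coproduct (both AICDs)
#' grows as `kcat * [E] * t`; the turnover number is the OLS slope of
#' total AICD vs time divided by the enzyme concentration.
#'
#' @param time_course Data.frame with columns `time` (hr) and
#'   `total_aicd` (nM), at least two distinct time points.
#' @param enzyme_conc Enzyme concentration (nM, > 0).
#' @return Estimated kcat (hr^-1).
#' @examples
#' tc <- data.frame(time = c(0, 8, 16), total_aicd = c(0, 480, 960))
#' recover_kcat(tc, enzyme_conc = 30)  # 2
#' @export
recover_kcat <- function(time_course, enzyme_conc) {
  time_course <- as.data.frame(time_course)
  if (!all(c("time", "total_aicd") %in% names(time_course))) {
    stop("`time_course` needs columns `time` and `total_aicd`", call. = FALSE)
  }
  if (!is.numeric(enzyme_conc) || enzyme_conc <= 0) {
    stop("`enzyme_conc` must be > 0", call. = FALSE)
  }
  t <- time_course$time
  y <- time_course$total_aicd
  if (length(t) < 2L || length(unique(t)) < 2L) {
    stop("need at least two distinct time points", call. = FALSE)
  }
  slope <- unname(stats::coef(stats::lm(y ~ t))[["t"]])
  slope / enzyme_conc
}

#' Recover branch and continuation probabilities from replicate tables
#'
#' Estimates the simulator's ground truth from (possibly noisy)
#' coproduct tables: each trimming step's q is the mean over replicates
#' of the per-replicate efficiency / 100 (nd replicates excluded), and
#' the Abeta49-branch probability is the mean per-replicate share of
#' AICD 50-99 in total AICD.  On noiseless expectation tables this
#' returns the configured parameters exactly.
#'
#' @param tables List of `coproduct_table`s (e.g. from
#'   [simulate_replicates()]).
#' @param graph A `pathway_graph`.
#' @return List with `continue_prob` (named numeric, `NA` where every
#'   replicate was nd) and `branch_p49`.
#' @export
recover_parameters <- function(tables, graph = default_pathway()) {
  if (inherits(tables, "coproduct_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "coproduct_table")))
  effs <- lapply(tables, function(ct) as.numeric(step_efficiencies(ct, graph)))
  eff_mat <- do.call(rbind, effs)
  colnames(eff_mat) <- names(step_efficiencies(tables[[1]], graph))
  q_hat <- apply(eff_mat, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) NA_real_ else mean(col) / 100
  })
  st <- graph_steps(graph)
  endo <- st[st$index == 1L, ]
  cp49 <- endo$coproduct[endo$product == "Ab49"]
  cp48 <- endo$coproduct[endo$product == "Ab48"]
  p49s <- vapply(tables, function(ct) {
    if (length(cp49) != 1L || length(cp48) != 1L) return(NA_real_)
    if (ct$status[[cp49]] != "ok" || ct$status[[cp48]] != "ok") return(NA_real_)
    tot <- ct$values[[cp49]] + ct$values[[cp48]]
    if (tot <= 0) NA_real_ else ct$values[[cp49]] / tot
  }, numeric(1))
  p49s <- p49s[!is.na(p49s)]
  list(continue_prob = q_hat,
       branch_p49 = if (length(p49s)) mean(p49s) else NA_real_)
}
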