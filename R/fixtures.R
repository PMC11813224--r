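## Packaged ground truth and named simulation scenarios.
##
## The packaged pool fixture holds the calculated concentration (nM) of
## each Abeta variant produced by wild-type and six FAD-mutant enzymes
## (two wild-type reactions, light- and heavy-isotope substrate, plus
## S169L, S170F, G378E, F386S, A431E, A434T).  nd cells (endoproteolysis
## coproducts of the near-null PALP-motif mutants below the 62.5 nM
## detection limit) are preserved as nd, and impossible negative pools
## are preserved for QC.

# Lowest AICD calibration standard; censoring limit for nd endo cells.
AICD_LOD <- 62.5

new_pool_table <- function(variant, pools, status,
                           efficiencies = NULL, extra_flags = empty_flags()) {
  flags <- extra_flags
  for (sp in names(pools)) {
    if (status[[sp]] == "ok" && pools[[sp]] < 0) {
      flags <- rbind(flags, new_flag("NEGATIVE_POOL", sp,
        sprintf("pool = %.4g nM < 0 (production < degradation coproduct)",
                pools[[sp]])))
    }
  }
  structure(
    list(variant = variant, pools = pools, status = status,
         ratio_42_40 = ab42_ab40_ratio_impl(pools, status),
         efficiencies = efficiencies, flags = order_flags(flags)),
    class = "pool_table"
  )
}

#' Packaged reference pool tables (eight enzyme reactions)
#'
#' Returns the calculated Abeta pool concentrations for the eight
#' reference reactions (WT-L, WT-H and the six PSEN1 FAD mutants) as a
#' named list of `pool_table`s, exactly as packaged: nd cells stay nd
#' and negative pools stay negative (with `NEGATIVE_POOL` flags).
#'
#' @return Named list of `pool_table` objects.
#' @examples
#' fx <- table1_fixture()
#' fx[["WT-L"]]$pools[["Ab42"]]   # 231.6
#' fx[["F386S"]]$pools[["Ab48"]]  # 634.8
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_pools.csv", package = "procleave")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  species <- graph_species(default_pathway())
  out <- list()
  for (v in unique(df$variant)) {
    sub <- df[df$variant == v, ]
    pools <- stats::setNames(rep(NA_real_, length(species)), species)
    status <- stats::setNames(rep("nd", length(species)), species)
    for (i in seq_len(nrow(sub))) {
      sp <- sub$species[i]
      if (!sp %in% species) stop("unknown species in fixture: ", sp,
                                 call. = FALSE)
      if (identical(sub$status[i], "OK")) {
        pools[sp] <- as.numeric(sub$value_nM[i])
        status[sp] <- "ok"
      }
    }
    out[[v]] <- new_pool_table(v, pools, status)
  }
  out
}

#' Coproduct table implied by a pool table (forward map)
#'
#' Applies the suffix-sum forward map to a pool row: the coproduct of
#' each step is the summed pools of its product and everything
#' downstream in the branch.  If any contributing pool is nd the
#' coproduct cannot be reconstructed and is emitted as
#' [censored()]`(lod)` (for the fixture rows this affects only the
#' endoproteolysis coproducts of A431E and A434T, which the assay could
#' not quantify below the lowest AICD standard).  This is the canonical
#' test input for the mass-balance inverse: running
#' [pools_from_coproducts()] on the result reproduces the numeric pool
#' cells exactly.
#'
#' @param pool_table A `pool_table` (e.g. one row of [table1_fixture()]).
#' @param graph A `pathway_graph`.
#' @param lod Censoring limit attached to non-reconstructable
#'   coproducts (default 62.5 nM, the lowest AICD standard).
#' @return A `coproduct_table`.
#' @export
implied_coproducts <- function(pool_table, graph = default_pathway(),
                               lod = AICD_LOD) {
  stopifnot(inherits(pool_table, "pool_table"))
  st <- graph_steps(graph)
  vals <- list()
  for (b in unique(st$branch)) {
    sb <- st[st$branch == b, ]
    p <- pool_table$pools[sb$product]
    suff <- rev(cumsum(rev(ifelse(is.na(p), 0, p))))
    has_na <- rev(cummax(rev(as.integer(is.na(p))))) == 1L
    for (i in seq_len(nrow(sb))) {
      vals[[sb$coproduct[i]]] <- if (has_na[i]) censored(lod) else suff[i]
    }
  }
  coproduct_table(vals, variant = pool_table$variant, graph = graph)
}

#' Named simulation scenarios
#'
#' Parameter sets that qualitatively reproduce the reference enzyme
#' phenotypes; they are illustrative, not fitted estimates.
#' \describe{
#'   \item{`"wt"`}{Wild-type-like: kcat 2 hr^-1, even branch split,
#'     continuation probabilities taken from the wild-type-implied
#'     efficiency profile (~0.90/0.60/0.66 on the Abeta40 branch,
#'     ~0.76/0.63/0.13 on the Abeta42 branch).}
#'   \item{`"f386s_like"`}{Trimming-deficient but endoproteolysis-
#'     competent: normal kcat, branch split shifted toward Abeta48,
#'     low q for Abeta43->Abeta40 and Abeta48->Abeta45, so Abeta43 and
#'     Abeta48 pools build up.}
#'   \item{`"endo_deficient"`}{Endoproteolysis-deficient (S169L/G378E-
#'     like): kcat reduced 10-fold, wild-type-like trimming.}
#'   \item{`"palp_like"`}{PALP-motif near-null (A431E/A434T-like): kcat
#'     reduced 40-fold so AICD production falls below the 62.5 nM
#'     detection floor; trimming also impaired.}
#' }
#'
#' @param name Scenario name (see above).
#' @return An object of class `scenario`: `name`, `params`
#'   (a [kinetic_params()]), `rationale`.
#' @examples
#' sc <- scenario("f386s_like")
#' expected_products(sc$params)$pools$pools[["Ab43"]]
#' @export
scenario <- function(name) {
  defs <- scenario_definitions()
  if (!name %in% names(defs)) {
    stop("unknown scenario '", name, "'; available: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  defs[[name]]
}

#' @rdname scenario
#' @export
scenario_names <- function() names(scenario_definitions())

scenario_definitions <- function() {
  wt_q <- c("Ab49->Ab46" = 0.90, "Ab46->Ab43" = 0.60, "Ab43->Ab40" = 0.66,
            "Ab48->Ab45" = 0.76, "Ab45->Ab42" = 0.63, "Ab42->Ab38" = 0.13)
  mk <- function(name, params, rationale) {
    structure(list(name = name, params = params, rationale = rationale),
              class = "scenario")
  }
  list(
    wt = mk("wt",
      kinetic_params(kcat = 2, branch_p49 = 0.5, continue_prob = wt_q,
                     noise_cv = 0.1, n_replicates = 4, seed = 101L),
      "Wild-type enzyme: efficient early trimming, modest final steps."),
    f386s_like = mk("f386s_like",
      kinetic_params(kcat = 2, branch_p49 = 0.25,
                     continue_prob = c("Ab49->Ab46" = 0.90,
                                       "Ab46->Ab43" = 0.60,
                                       "Ab43->Ab40" = 0.15,
                                       "Ab48->Ab45" = 0.25,
                                       "Ab45->Ab42" = 0.50,
                                       "Ab42->Ab38" = 0.10),
                     noise_cv = 0.1, n_replicates = 4, seed = 102L),
      paste("Endoproteolysis-competent but deficient in Abeta43->Abeta40",
            "and Abeta48->Abeta45 trimming; Abeta43 and Abeta48 build up.")),
    endo_deficient = mk("endo_deficient",
      kinetic_params(kcat = 0.2, branch_p49 = 0.5, continue_prob = wt_q,
                     noise_cv = 0.1, n_replicates = 4, seed = 103L),
      "Reduced epsilon cleavage with near-normal trimming profile."),
    palp_like = mk("palp_like",
      kinetic_params(kcat = 0.05, branch_p49 = 0.5,
                     continue_prob = c("Ab49->Ab46" = 0.9,
                                       "Ab46->Ab43" = 0.6,
                                       "Ab43->Ab40" = 0.5,
                                       "Ab48->Ab45" = 0.5,
                                       "Ab45->Ab42" = 0.5,
                                       "Ab42->Ab38" = 0.3),
                     noise_cv = 0.1, n_replicates = 4, seed = 104L),
      paste("Near-null PALP-motif mutant: AICD production (24 nM in 16 hr)",
            "falls below the 62.5 nM detection floor."))
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$name, "\n  ", x$rationale, "\n", sep = "")
  cat("  kcat ", x$params$kcat, " hr^-1, p49 ", x$params$branch_p49,
      ", q = [", paste(signif(x$params$continue_prob, 3), collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}
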