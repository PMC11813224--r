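## Mass-balance maps between Abeta pools and cleavage coproducts.
##
## Each cleavage event releases exactly one coproduct, so coproduct
## concentrations count events.  For a linear branch the coproduct of
## step i equals the summed pools of everything at or downstream of the
## step-i product (suffix sum); the inverse is pool(X) = producing
## coproduct - consuming coproduct.  The forward map is unitriangular,
## hence exactly invertible.

QC_CODES <- c("NEGATIVE_POOL", "EFFICIENCY_GT_100", "PRECURSOR_ND", "BELOW_LOD")

#' Mark a measurement as censored at a detection limit
#'
#' Concentrations that fall below the lowest calibration standard cannot
#' be quantified and are reported as not determined (nd), carrying the
#' censoring limit.
#'
#' @param limit Detection limit (nM) below which the value fell.
#' @return An object of class `censored_value`.
#' @examples
#' censored(62.5)
#' @export
censored <- function(limit) {
  stopifnot(is.numeric(limit), length(limit) == 1L, is.finite(limit), limit >= 0)
  structure(list(limit = as.numeric(limit)), class = "censored_value")
}

#' @export
print.censored_value <- function(x, ...) {
  cat("<censored below ", format(x$limit), " nM>\n", sep = "")
  invisible(x)
}

is_censored <- function(x) inherits(x, "censored_value")

#' Coproduct concentration table for one reaction
#'
#' Holds the measured concentrations (nM) of every coproduct of a
#' pathway for one enzyme variant, replicate and isotope channel.
#' Entries may be numeric, [censored()] (below the detection limit) or
#' `NA` (missing).
#'
#' @param values Named list or numeric vector keyed by coproduct id;
#'   must contain every coproduct of `graph`.  Numeric entries must be
#'   finite and non-negative; use [censored()] for below-LOD entries and
#'   `NA` for missing ones.
#' @param variant Enzyme variant label (e.g. `"WT-L"`, `"S170F"`).
#' @param replicate Replicate number (integer >= 1).
#' @param channel Isotope channel, `"light"` or `"heavy"`.
#' @param graph A `pathway_graph`; defaults to [default_pathway()].
#' @return An object of class `coproduct_table` with fields `values`
#'   (named numeric, `NA` where not quantified), `status` (named,
#'   `"ok"`/`"censored"`/`"missing"`), `limit` (named numeric censoring
#'   limits), `variant`, `replicate`, `channel`.
#' @export
coproduct_table <- function(values, variant = "", replicate = 1L,
                            channel = c("light", "heavy"),
                            graph = default_pathway()) {
  channel <- match.arg(channel)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) {
    stop("`replicate` must be an integer >= 1", call. = FALSE)
  }
  ids <- graph_coproducts(graph)
  if (is.null(names(values)) || !all(ids %in% names(values))) {
    missing_ids <- setdiff(ids, names(values))
    stop("missing coproduct key(s): ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(values), ids)
  if (length(extra)) {
    stop("unknown coproduct id(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  val <- stats::setNames(rep(NA_real_, length(ids)), ids)
  status <- stats::setNames(rep("ok", length(ids)), ids)
  limit <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (id in ids) {
    v <- if (is.list(values)) values[[id]] else values[[id]]
    if (is_censored(v)) {
      status[id] <- "censored"
      limit[id] <- v$limit
    } else if (is.null(v) || (length(v) == 1L && is.na(v))) {
      status[id] <- "missing"
    } else {
      if (!is.numeric(v) || length(v) != 1L) {
        stop("entry for ", id, " must be a single number, censored() or NA",
             call. = FALSE)
      }
      if (!is.finite(v)) stop("entry for ", id, " is not finite", call. = FALSE)
      val[id] <- as.numeric(v)
    }
  }
  structure(
    list(values = val, status = status, limit = limit,
         variant = variant, replicate = replicate, channel = channel),
    class = "coproduct_table"
  )
}

#' @export
print.coproduct_table <- function(x, ...) {
  cat("<coproduct_table> variant=", x$variant, " rep=", x$replicate,
      " channel=", x$channel, "\n", sep = "")
  shown <- ifelse(x$status == "ok", formatC(x$values, format = "fg"),
                  ifelse(x$status == "censored",
                         paste0("<", format(x$limit), " (nd)"), "NA"))
  print(stats::setNames(shown, names(x$values)), quote = FALSE)
  invisible(x)
}

new_flag <- function(code, target, detail = "") {
  stopifnot(code %in% QC_CODES)
  data.frame(code = code, target = target, detail = detail,
             stringsAsFactors = FALSE)
}

empty_flags <- function() {
  data.frame(code = character(), target = character(), detail = character(),
             stringsAsFactors = FALSE)
}

order_flags <- function(flags) {
  flags <- unique(flags)
  flags[order(flags$code, flags$target), , drop = FALSE]
}

#' Forward map: coproduct concentrations implied by Abeta pools
#'
#' Under mass balance every molecule that reaches Abeta-x in a branch
#' released the coproducts of all steps up to x, so the coproduct of
#' step i equals the sum of the pools of the step-i product and all
#' downstream species of that branch (suffix sums).  The terminal
#' coproduct equals the terminal pool and the endoproteolysis coproduct
#' equals the whole-branch pool sum.
#'
#' @param pools Named numeric vector of pool concentrations (nM), keyed
#'   by species id; every species of `graph` must be present and finite
#'   (negative values are allowed - they propagate).
#' @param graph A `pathway_graph`.
#' @return Named numeric vector of coproduct concentrations (nM), one
#'   entry per coproduct of `graph`.
#' @examples
#' g <- default_pathway()
#' pools <- c(Ab49 = 56.0, Ab46 = 201.7, Ab43 = 103.3, Ab40 = 196.9,
#'            Ab48 = 131.5, Ab45 = 153.3, Ab42 = 231.6, Ab38 = 34.2)
#' coproducts_from_pools(pools, g)
#' @export
coproducts_from_pools <- function(pools, graph = default_pathway()) {
  st <- graph_steps(graph)
  species <- st$product
  if (is.null(names(pools)) || !all(species %in% names(pools))) {
    stop("missing pool value(s) for: ",
         paste(setdiff(species, names(pools)), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(pools), species)
  if (length(extra)) {
    stop("unknown species id(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(pools))) {
    stop("pool values must all be finite", call. = FALSE)
  }
  out <- stats::setNames(numeric(nrow(st)), st$coproduct)
  for (b in unique(st$branch)) {
    sb <- st[st$branch == b, ]
    p <- as.numeric(pools[sb$product])
    out[sb$coproduct] <- rev(cumsum(rev(p)))  # suffix sums
  }
  out
}

#' Inverse map: Abeta pools from measured coproducts
#'
#' Implements the mass-balance relation pool(Abeta-x) = \[coproduct of
#' the step producing x\] - \[coproduct of the step consuming x\]; terminal
#' species keep their producing coproduct.  Negative pools are preserved
#' (they are the quality-control signal for inconsistent coproduct
#' quantification) and flagged `NEGATIVE_POOL`.  A pool whose defining
#' coproduct is censored is `NA` (nd) with flag `BELOW_LOD`; one whose
#' defining coproduct is missing is `NA` with flag `PRECURSOR_ND`.
#'
#' The returned table also carries the per-step cleavage efficiencies
#' (see [step_efficiencies()]) and the Abeta42/Abeta40 ratio.
#'
#' @param coproducts A [coproduct_table()], or a named numeric vector of
#'   coproduct concentrations (converted with defaults).
#' @param graph A `pathway_graph`.
#' @return An object of class `pool_table`: fields `variant`, `pools`
#'   (named numeric, `NA` = nd), `status` (named, `"ok"`/`"nd"`),
#'   `ratio_42_40` (numeric or `NA`), `efficiencies`
#'   (a `step_efficiencies` object) and `flags` (data.frame
#'   `code`/`target`/`detail`).
#' @examples
#' g <- default_pathway()
#' cp <- coproduct_table(
#'   c(`AICD49-99` = 862.5, VIT = 227.7, TVI = 47.6, VVIA = 4.3,
#'     `AICD50-99` = 446.4, ITL = 405.0, VIV = 182.1, IAT = 41.2),
#'   variant = "F386S")
#' pools_from_coproducts(cp, g)$pools[["Ab48"]]  # 634.8
#' @export
pools_from_coproducts <- function(coproducts, graph = default_pathway()) {
  if (!inherits(coproducts, "coproduct_table")) {
    coproducts <- coproduct_table(coproducts, graph = graph)
  }
  st <- graph_steps(graph)
  val <- coproducts$values
  cstat <- coproducts$status

  pools <- stats::setNames(rep(NA_real_, nrow(st)), st$product)
  pstat <- stats::setNames(rep("ok", nrow(st)), st$product)
  flags <- empty_flags()

  for (b in unique(st$branch)) {
    sb <- st[st$branch == b, ]
    for (i in seq_len(nrow(sb))) {
      sp <- sb$product[i]
      producing <- sb$coproduct[i]
      consuming <- if (i < nrow(sb)) sb$coproduct[i + 1L] else NA_character_
      defining <- c(producing, consuming)
      defining <- defining[!is.na(defining)]
      def_stat <- cstat[defining]
      if (any(def_stat != "ok")) {
        pstat[sp] <- "nd"
        if (any(def_stat == "censored")) {
          flags <- rbind(flags, new_flag("BELOW_LOD", sp,
            paste0("defining coproduct below detection limit: ",
                   paste(defining[def_stat == "censored"], collapse = ", "))))
        }
        if (any(def_stat == "missing")) {
          flags <- rbind(flags, new_flag("PRECURSOR_ND", sp,
            paste0("defining coproduct missing: ",
                   paste(defining[def_stat == "missing"], collapse = ", "))))
        }
        next
      }
      p <- if (is.na(consuming)) val[[producing]] else
        val[[producing]] - val[[consuming]]
      pools[sp] <- p
      if (p < 0) {
        flags <- rbind(flags, new_flag("NEGATIVE_POOL", sp,
          sprintf("pool = %.4g nM < 0 (production < degradation coproduct)", p)))
      }
    }
  }

  eff <- step_efficiencies(coproducts, graph)
  flags <- rbind(flags, attr(eff, "flags"))

  ratio <- ab42_ab40_ratio_impl(pools, pstat)

  structure(
    list(variant = coproducts$variant, pools = pools, status = pstat,
         ratio_42_40 = ratio, efficiencies = eff,
         flags = order_flags(flags)),
    class = "pool_table"
  )
}

#' @export
print.pool_table <- function(x, ...) {
  cat("<pool_table> variant=", x$variant, "\n", sep = "")
  shown <- ifelse(x$status == "ok", formatC(x$pools, format = "fg"), "nd")
  print(stats::setNames(shown, names(x$pools)), quote = FALSE)
  cat("Ab42/Ab40 ratio: ",
      if (is.na(x$ratio_42_40)) "nd" else format(round(x$ratio_42_40, 3)),
      "\n", sep = "")
  if (nrow(x$flags)) {
    cat("QC flags:\n")
    print(x$flags, row.names = FALSE)
  }
  invisible(x)
}

#' Per-step cleavage efficiencies
#'
#' The percent cleavage efficiency of trimming step Abeta-x -> Abeta-y
#' answers: of the Abeta-x that was produced, how much was cleaved in
#' the next step?  It is `100 * [coproduct of x->y] / [coproduct of the
#' step producing x]`.  Endoproteolysis steps have no upstream coproduct
#' and hence no efficiency.  If the producing coproduct is zero,
#' censored or missing the efficiency is nd (`NA`).  Values above 100%
#' are impossible (more precursor consumed than produced) but are
#' returned unclipped and flagged `EFFICIENCY_GT_100` - they diagnose
#' under- or over-detection of a coproduct.
#'
#' @inheritParams pools_from_coproducts
#' @return Named numeric vector over trimming step ids
#'   (`"Ab49->Ab46"`, ...), `NA` = nd, of class `step_efficiencies`,
#'   with attributes `status` (`"ok"`/`"nd"`) and `flags` (data.frame).
#' @examples
#' cp <- c(`AICD49-99` = 133.4, VIT = 306.9, TVI = 85.7, VVIA = 4.9,
#'         `AICD50-99` = 231.8, ITL = 193.4, VIV = 65.1, IAT = 67.9)
#' eff <- step_efficiencies(coproduct_table(cp, variant = "S170F"))
#' eff[["Ab48->Ab45"]]  # > 200, flagged
#' @export
step_efficiencies <- function(coproducts, graph = default_pathway()) {
  if (!inherits(coproducts, "coproduct_table")) {
    coproducts <- coproduct_table(coproducts, graph = graph)
  }
  st <- graph_steps(graph)
  trims <- st[st$index > 1L, ]
  eff <- stats::setNames(rep(NA_real_, nrow(trims)), trims$step)
  status <- stats::setNames(rep("ok", nrow(trims)), trims$step)
  flags <- empty_flags()
  for (i in seq_len(nrow(trims))) {
    id <- trims$step[i]
    this_cp <- trims$coproduct[i]
    # coproduct of the step producing the precursor = previous step in branch
    prev <- st[st$branch == trims$branch[i] & st$index == trims$index[i] - 1L, ]
    prev_cp <- prev$coproduct
    ok_prev <- coproducts$status[[prev_cp]] == "ok" &&
      coproducts$values[[prev_cp]] != 0
    ok_this <- coproducts$status[[this_cp]] == "ok"
    if (!ok_prev || !ok_this) {
      status[id] <- "nd"
      next
    }
    e <- 100 * coproducts$values[[this_cp]] / coproducts$values[[prev_cp]]
    eff[id] <- e
    if (e > 100) {
      flags <- rbind(flags, new_flag("EFFICIENCY_GT_100", id,
        sprintf("efficiency = %.1f%% exceeds 100%%", e)))
    }
  }
  structure(eff, status = status, flags = order_flags(flags),
            class = c("step_efficiencies", "numeric"))
}

ab42_ab40_ratio_impl <- function(pools, status) {
  if (!all(c("Ab42", "Ab40") %in% names(pools))) return(NA_real_)
  if (status[["Ab42"]] != "ok" || status[["Ab40"]] != "ok") return(NA_real_)
  if (pools[["Ab40"]] <= 0) return(NA_real_)
  unname(pools[["Ab42"]] / pools[["Ab40"]])
}

#' Abeta42/Abeta40 ratio of a pool table
#'
#' The ratio of aggregation-prone Abeta42 to soluble Abeta40, the
#' classical FAD biomarker.  Returns `NA` (nd) if either pool is nd or
#' the Abeta40 pool is non-positive (a non-positive denominator makes
#' the ratio unreliable, as for the near-null PALP-motif mutants).
#'
#' @param pool_table A `pool_table` from [pools_from_coproducts()].
#' @return A single number, or `NA` for nd.
#' @export
ab42_ab40_ratio <- function(pool_table) {
  stopifnot(inherits(pool_table, "pool_table"))
  ab42_ab40_ratio_impl(pool_table$pools, pool_table$status)
}

#' Aggregate QC flags across pool tables
#'
#' Collects every quality-control flag (negative pools, impossible
#' efficiencies, censored/missing inputs) from a list of pool tables
#' into one deterministic report, ordered by variant, flag code, target.
#'
#' @param pool_tables A `pool_table` or list of them.
#' @return A data.frame with columns `variant`, `code`, `target`,
#'   `detail` (zero rows if nothing was flagged).
#' @export
qc_report <- function(pool_tables) {
  if (inherits(pool_tables, "pool_table")) pool_tables <- list(pool_tables)
  stopifnot(length(pool_tables) >= 1L,
            all(vapply(pool_tables, inherits, TRUE, "pool_table")))
  rows <- lapply(pool_tables, function(pt) {
    if (nrow(pt$flags) == 0L) return(NULL)
    cbind(variant = pt$variant, pt$flags)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(variant = character(), code = character(),
                      target = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$variant, out$code, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
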