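## End-to-end orchestration: measurements (or simulation) -> calibration
## -> mass-balance pools -> efficiencies -> QC -> group statistics.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two groups of concentrations with an unpaired t-test
#'
#' Two-sided unpaired t-test between replicate values of a quantity for
#' two enzyme variants.  Student's pooled-variance test is the default;
#' Welch's is available.  nd (`NA`) observations are excluded and
#' counted; fewer than two numeric values in either group yields an nd
#' result with a reason rather than an error.  Significance stars
#' follow the usual thresholds (`*` p<0.05, `**` p<0.01, `***`
#' p<0.001).  Degenerate zero-variance data are handled explicitly:
#' identical constant groups give t = 0, p = 1; separated constant
#' groups give infinite t and p = 0.
#'
#' @param values_a,values_b Numeric vectors (nM or percent); `NA` = nd.
#' @param test `"student"` (pooled variance) or `"welch"`.
#' @param quantity,label_a,label_b Identifiers copied into the result.
#' @return One-row data.frame: `quantity`, `group_a`, `group_b`,
#'   `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`, `n_excluded`,
#'   `t`, `p`, `stars`, `status` (`"OK"`/`"ND"`), `reason`.
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(2, 3, 4, 5))
#' @export
compare_groups <- function(values_a, values_b, test = c("student", "welch"),
                           quantity = "", label_a = "A", label_b = "B") {
  test <- match.arg(test)
  n_excluded <- sum(is.na(values_a)) + sum(is.na(values_b))
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  res <- data.frame(
    quantity = quantity, group_a = label_a, group_b = label_b,
    mean_a = if (length(a)) mean(a) else NA_real_,
    sd_a = if (length(a) > 1) stats::sd(a) else NA_real_,
    n_a = length(a),
    mean_b = if (length(b)) mean(b) else NA_real_,
    sd_b = if (length(b) > 1) stats::sd(b) else NA_real_,
    n_b = length(b),
    n_excluded = n_excluded,
    t = NA_real_, p = NA_real_, stars = "", status = "ND", reason = "",
    stringsAsFactors = FALSE)
  if (length(a) < 2L || length(b) < 2L) {
    res$reason <- "fewer than 2 numeric values in a group"
    return(res)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res$t <- 0; res$p <- 1
    } else {
      res$t <- sign(mean(a) - mean(b)) * Inf; res$p <- 0
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = (test == "student"),
                        alternative = "two.sided")
    res$t <- unname(ht$statistic)
    res$p <- ht$p.value
  }
  res$stars <- significance_stars(res$p)
  res$status <- "OK"
  res
}

significance_stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path",
                             call. = FALSE)
  mode <- config$mode %||% stop("config needs a `mode`", call. = FALSE)
  if (!mode %in% c("measured", "measured_raw", "simulate")) {
    stop("mode must be one of measured, measured_raw, simulate",
         call. = FALSE)
  }
  if (mode %in% c("measured", "measured_raw") &&
      is.null(config$measurements)) {
    stop("measured modes need a `measurements` path", call. = FALSE)
  }
  if (mode == "measured_raw" && is.null(config$standards)) {
    stop("measured_raw mode needs a `standards` path", call. = FALSE)
  }
  if (mode == "measured_raw" && !file.exists(config$standards)) {
    stop("standards file not found: ", config$standards, call. = FALSE)
  }
  if (mode == "simulate" && is.null(config$scenarios) &&
      is.null(config$params)) {
    stop("simulate mode needs `scenarios` (names) or `params`", call. = FALSE)
  }
  config
}

load_raw_measurements <- function(path, curves, graph) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("variant", "replicate", "channel", "coproduct",
                        "analyte_response", "internal_standard_response"),
                  path)
  bad <- setdiff(unique(df$coproduct), graph_coproducts(graph))
  if (length(bad)) stop("unknown coproduct id(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  no_curve <- setdiff(unique(df$coproduct), names(curves))
  if (length(no_curve)) {
    stop("no standard curve for analyte(s): ",
         paste(no_curve, collapse = ", "), call. = FALSE)
  }
  df$ratio <- internal_standard_ratio(df$analyte_response,
                                      df$internal_standard_response)
  keys <- unique(df[, c("variant", "replicate", "channel")])
  keys <- keys[order(keys$variant, keys$replicate, keys$channel), ,
               drop = FALSE]
  lapply(seq_len(nrow(keys)), function(k) {
    sel <- df$variant == keys$variant[k] &
      df$replicate == keys$replicate[k] & df$channel == keys$channel[k]
    sub <- df[sel, ]
    vals <- list()
    for (i in seq_len(nrow(sub))) {
      vals[[sub$coproduct[i]]] <-
        invert_curve(curves[[sub$coproduct[i]]], sub$ratio[i])
    }
    coproduct_table(vals, variant = keys$variant[k],
                    replicate = keys$replicate[k],
                    channel = keys$channel[k], graph = graph)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates one run: obtain coproduct tables (from a measurements
#' CSV, from raw responses calibrated against a standards CSV, or by
#' simulation from named scenarios / kinetic parameters), invert to
#' Abeta pools, compute per-step efficiencies, aggregate QC flags, and
#' compare every variant against a reference with unpaired t-tests.
#' The run is a pure function of (inputs, config, seed); with an
#' `out_dir` the tidy CSVs are identical on rerun.
#'
#' Config fields: `mode` (`"measured"`, `"measured_raw"`,
#' `"simulate"`); `measurements`, `standards` (paths, measured modes);
#' `scenarios` (scenario names) or `params` (a [kinetic_params()]
#' argument list) for simulate mode; `pathway` (optional YAML path,
#' default topology otherwise); `reference` (variant for statistics,
#' default `"WT-L"` if present else the first variant); `test`
#' (`"student"`/`"welch"`); `seed`; `out_dir`.
#'
#' @param config A list, or path to a YAML file with the fields above.
#' @return A result bundle (list) with `coproduct_tables`,
#'   `pool_tables`, `qc` (data.frame), `stats` (data.frame),
#'   `manifest`; written to `config$out_dir` when given.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  graph <- if (!is.null(config$pathway)) read_pathway(config$pathway)
           else default_pathway()
  seed <- as.integer(config$seed %||% 1L)

  tables <- switch(config$mode,
    measured = load_measurements(config$measurements, graph),
    measured_raw = {
      standards <- load_standards(config$standards)
      curves <- lapply(names(standards), function(a) {
        fit_standard_curve(standards[[a]], analyte = a,
                           force_origin = isTRUE(config$force_origin),
                           log_log = isTRUE(config$log_log))
      })
      names(curves) <- names(standards)
      load_raw_measurements(config$measurements, curves, graph)
    },
    simulate = {
      if (!is.null(config$scenarios)) {
        tabs <- list()
        for (i in seq_along(config$scenarios)) {
          sc <- scenario(config$scenarios[[i]])
          params <- sc$params
          params$seed <- seed + i - 1L
          tabs <- c(tabs, simulate_replicates(params, graph,
                                              variant = sc$name))
        }
        tabs
      } else {
        args <- config$params
        args$seed <- args$seed %||% seed
        params <- do.call(kinetic_params, args)
        simulate_replicates(params, graph,
                            variant = config$variant %||% "simulated")
      }
    })

  pool_tables <- lapply(tables, function(ct) {
    pt <- pools_from_coproducts(ct, graph)
    pt$replicate <- ct$replicate
    pt
  })

  qc <- qc_report(pool_tables)
  stats_df <- pipeline_stats(pool_tables,
                             reference = config$reference,
                             test = config$test %||% "student")

  manifest <- list(
    package = "procleave",
    version = as.character(utils::packageVersion("procleave")),
    mode = config$mode,
    seed = seed,
    n_tables = length(tables),
    config_hash = config_hash(config)
  )
  bundle <- list(coproduct_tables = tables, pool_tables = pool_tables,
                 qc = qc, stats = stats_df, manifest = manifest)
  if (!is.null(config$out_dir)) write_tables(bundle, config$out_dir)
  invisible(bundle)
}

config_hash <- function(config) {
  config$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

# Gather per-replicate values of every quantity and run variant-vs-
# reference comparisons.
pipeline_stats <- function(pool_tables, reference = NULL, test = "student") {
  variants <- unique(vapply(pool_tables, `[[`, "", "variant"))
  if (length(variants) < 2L) {
    return(data.frame(quantity = character(), group_a = character(),
                      group_b = character(), mean_a = numeric(),
                      sd_a = numeric(), n_a = integer(), mean_b = numeric(),
                      sd_b = numeric(), n_b = integer(),
                      n_excluded = integer(), t = numeric(), p = numeric(),
                      stars = character(), status = character(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  reference <- reference %||%
    (if ("WT-L" %in% variants) "WT-L" else variants[1])
  if (!reference %in% variants) {
    stop("reference variant '", reference, "' not present", call. = FALSE)
  }
  values_of <- function(variant, getter) {
    unlist(lapply(pool_tables[vapply(pool_tables, `[[`, "",
                                     "variant") == variant], getter))
  }
  quantities <- list()
  sp <- names(pool_tables[[1]]$pools)
  for (s in sp) {
    quantities[[paste0("pool:", s)]] <- local({
      s <- s
      function(pt) if (pt$status[[s]] == "ok") pt$pools[[s]] else NA_real_
    })
  }
  if (!is.null(pool_tables[[1]]$efficiencies)) {
    for (st_id in names(pool_tables[[1]]$efficiencies)) {
      quantities[[paste0("efficiency:", st_id)]] <- local({
        st_id <- st_id
        function(pt) {
          e <- pt$efficiencies
          if (attr(e, "status")[[st_id]] == "ok") e[[st_id]] else NA_real_
        }
      })
    }
  }
  quantities[["ratio:Ab42/Ab40"]] <- function(pt) pt$ratio_42_40

  rows <- list()
  for (v in setdiff(variants, reference)) {
    for (qn in names(quantities)) {
      rows[[length(rows) + 1L]] <- compare_groups(
        values_of(v, quantities[[qn]]),
        values_of(reference, quantities[[qn]]),
        test = test, quantity = qn, label_a = v, label_b = reference)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
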