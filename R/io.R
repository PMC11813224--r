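## CSV dialects of the pipeline.
##
## Measurements: one row per (variant, replicate, channel, coproduct).
## Cells are plain numbers, "NA" for missing, or "CENSORED<limit>"
## (e.g. "CENSORED62.5") for values below the detection limit.  UTF-8,
## "." decimal separator throughout.

parse_cell <- function(x, where) {
  x <- trimws(x)
  if (is.na(x) || x == "" || toupper(x) == "NA") return(NA)
  if (grepl("^CENSORED", x, ignore.case = TRUE)) {
    lim <- suppressWarnings(as.numeric(sub("^CENSORED", "", x,
                                           ignore.case = TRUE)))
    if (is.na(lim)) stop("malformed censored token '", x, "' at ", where,
                         call. = FALSE)
    return(censored(lim))
  }
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("non-numeric value '", x, "' at ", where, call. = FALSE)
  v
}

format_cell <- function(value, status, limit) {
  if (status == "ok") format(value, digits = 15, scientific = FALSE)
  else if (status == "censored") paste0("CENSORED", format(limit, digits = 15))
  else "NA"
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read coproduct measurement tables
#'
#' Reads a measurements CSV with columns `variant`, `replicate`,
#' `channel` (`light`/`heavy`), `coproduct`, `value` (nM;
#' `CENSORED<limit>` for below-LOD, `NA` for missing) and returns one
#' [coproduct_table()] per (variant, replicate, channel).  Schema
#' violations (missing columns, unknown coproduct or channel, negative
#' or non-numeric concentrations) fail with a message naming the
#' offending column or row.
#'
#' @param path CSV file path.
#' @param graph A `pathway_graph` defining the expected coproduct ids.
#' @return List of `coproduct_table`s, ordered by variant, replicate,
#'   channel.
#' @export
load_measurements <- function(path, graph = default_pathway()) {
  if (!file.exists(path)) stop("measurements file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  require_columns(df, c("variant", "replicate", "channel", "coproduct",
                        "value"), path)
  ids <- graph_coproducts(graph)
  bad <- setdiff(unique(df$coproduct), ids)
  if (length(bad)) {
    stop("file '", path, "' has unknown coproduct id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_ch <- setdiff(unique(df$channel), c("light", "heavy"))
  if (length(bad_ch)) {
    stop("file '", path, "' has invalid channel value(s): ",
         paste(bad_ch, collapse = ", "), call. = FALSE)
  }
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate)) || any(df$replicate < 1L)) {
    stop("column `replicate` must hold integers >= 1", call. = FALSE)
  }
  keys <- unique(df[, c("variant", "replicate", "channel")])
  keys <- keys[order(keys$variant, keys$replicate, keys$channel), ,
               drop = FALSE]
  out <- vector("list", nrow(keys))
  for (k in seq_len(nrow(keys))) {
    sel <- df$variant == keys$variant[k] &
      df$replicate == keys$replicate[k] & df$channel == keys$channel[k]
    sub <- df[sel, ]
    if (anyDuplicated(sub$coproduct)) {
      stop("duplicate coproduct rows for variant ", keys$variant[k],
           " replicate ", keys$replicate[k], call. = FALSE)
    }
    vals <- list()
    for (i in seq_len(nrow(sub))) {
      v <- parse_cell(sub$value[i],
                      paste0("row ", rownames(sub)[i], " (", sub$coproduct[i], ")"))
      if (is.numeric(v) && length(v) == 1L && !is.na(v) && v < 0) {
        stop("negative concentration for ", sub$coproduct[i], " in variant ",
             keys$variant[k], call. = FALSE)
      }
      vals[[sub$coproduct[i]]] <- v
    }
    out[[k]] <- coproduct_table(vals, variant = keys$variant[k],
                                replicate = keys$replicate[k],
                                channel = keys$channel[k], graph = graph)
  }
  out
}

#' Write coproduct tables in the measurements dialect
#'
#' Inverse of [load_measurements()]: `load_measurements(write_measurements(x))`
#' round-trips exactly.
#'
#' @param tables List of `coproduct_table`s.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(tables, path) {
  if (inherits(tables, "coproduct_table")) tables <- list(tables)
  rows <- lapply(tables, function(ct) {
    data.frame(
      variant = ct$variant, replicate = ct$replicate, channel = ct$channel,
      coproduct = names(ct$values),
      value = vapply(names(ct$values), function(id) {
        format_cell(ct$values[[id]], ct$status[[id]], ct$limit[[id]])
      }, ""),
      stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a standards table
#'
#' Reads a calibration standards CSV with columns `analyte`,
#' `concentration_nM`, `analyte_response`,
#' `internal_standard_response`, computes the internal-standard
#' response ratio, and returns per-analyte point sets ready for
#' [fit_standard_curve()].
#'
#' @param path CSV file path.
#' @return Named list (by analyte) of data.frames with columns
#'   `concentration`, `response`.
#' @export
load_standards <- function(path) {
  if (!file.exists(path)) stop("standards file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("analyte", "concentration_nM", "analyte_response",
                        "internal_standard_response"), path)
  if (any(!is.finite(df$concentration_nM)) || any(df$concentration_nM <= 0)) {
    stop("column `concentration_nM` must be positive and numeric",
         call. = FALSE)
  }
  ratio <- internal_standard_ratio(df$analyte_response,
                                   df$internal_standard_response)
  out <- list()
  for (a in unique(df$analyte)) {
    sel <- df$analyte == a
    out[[a]] <- data.frame(concentration = df$concentration_nM[sel],
                           response = ratio[sel])
  }
  out
}

pool_tables_to_df <- function(pool_tables) {
  rows <- lapply(pool_tables, function(pt) {
    flags_by_sp <- vapply(names(pt$pools), function(sp) {
      f <- pt$flags[pt$flags$target == sp, "code"]
      paste(f, collapse = ";")
    }, "")
    data.frame(
      variant = pt$variant, replicate = pt$replicate %||% 1L,
      species = names(pt$pools),
      value = ifelse(pt$status == "ok",
                     format(pt$pools, digits = 15, scientific = FALSE), "NA"),
      status = ifelse(pt$status == "ok", "OK", "ND"),
      flags = flags_by_sp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

efficiencies_to_df <- function(pool_tables) {
  rows <- lapply(pool_tables, function(pt) {
    eff <- pt$efficiencies
    if (is.null(eff)) return(NULL)
    status <- attr(eff, "status")
    flags <- attr(eff, "flags")
    flags_by_step <- vapply(names(eff), function(s) {
      paste(flags[flags$target == s, "code"], collapse = ";")
    }, "")
    data.frame(
      variant = pt$variant, replicate = pt$replicate %||% 1L,
      step = names(eff),
      value = ifelse(status == "ok",
                     format(as.numeric(eff), digits = 15, scientific = FALSE),
                     "NA"),
      status = ifelse(status == "ok", "OK", "ND"),
      flags = flags_by_step, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(variant = character(), replicate = integer(),
                      step = character(), value = character(),
                      status = character(), flags = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a result bundle as tidy CSVs
#'
#' Writes `pools.csv`, `efficiencies.csv`, `qc.csv`, `stats.csv` and
#' `manifest.json` into `dir`.  Output is a pure function of the bundle,
#' so re-running a deterministic pipeline reproduces the files
#' byte-for-byte.
#'
#' @param bundle A result bundle from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(pool_tables_to_df(bundle$pool_tables),
                   file.path(dir, "pools.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(efficiencies_to_df(bundle$pool_tables),
                   file.path(dir, "efficiencies.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(bundle$qc, file.path(dir, "qc.csv"), row.names = FALSE)
  utils::write.csv(bundle$stats, file.path(dir, "stats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
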