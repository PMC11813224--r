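#' Pathway graph for processive proteolysis of C99
#'
#' gamma-secretase processes the APP C-terminal fragment C99 along two
#' branches.  Initial endoproteolysis (epsilon cleavage) yields either
#' Abeta49 plus AICD 50-99 or Abeta48 plus AICD 49-99; carboxypeptidase
#' trimming then removes tri-/tetrapeptides:
#'
#' \preformatted{
#'   C99 -> Ab49 -> Ab46 -> Ab43 -> Ab40   (coproducts AICD50-99, ITL, VIV, IAT)
#'   C99 -> Ab48 -> Ab45 -> Ab42 -> Ab38   (coproducts AICD49-99, VIT, TVI, VVIA)
#' }
#'
#' A `pathway_graph` is an ordered list of branches; each branch is an
#' ordered list of steps with fields `precursor`, `product`, `coproduct`
#' and (for trimming steps) the literal coproduct peptide sequence.  Each
#' coproduct belongs to exactly one step and each non-terminal species is
#' the precursor of exactly one step, so the concentration of a coproduct
#' counts the cleavage events of its step.
#'
#' @param branches List of branches, each a list of steps. Each step is a
#'   list with elements `precursor`, `product`, `coproduct` and optionally
#'   `sequence` (amino-acid string of the released peptide).
#' @return An object of class `pathway_graph`.
#' @seealso [default_pathway()], [coproducts_from_pools()],
#'   [pools_from_coproducts()]
#' @export
pathway_graph <- function(branches) {
  if (!is.list(branches) || length(branches) < 1L) {
    stop("`branches` must be a non-empty list of branches", call. = FALSE)
  }
  steps <- unlist(branches, recursive = FALSE)
  need <- c("precursor", "product", "coproduct")
  for (s in steps) {
    if (!all(need %in% names(s))) {
      stop("each step needs fields precursor, product, coproduct", call. = FALSE)
    }
  }
  cps <- vapply(steps, `[[`, "", "coproduct")
  if (anyDuplicated(cps)) {
    stop("each coproduct must appear in exactly one step", call. = FALSE)
  }
  # the shared substrate starts every branch; downstream precursors (the
  # branch intermediates) must each feed exactly one step
  trim_pre <- unlist(lapply(branches, function(b) {
    vapply(b[-1], `[[`, "", "precursor")
  }))
  if (anyDuplicated(trim_pre)) {
    stop("each intermediate may be the precursor of at most one step",
         call. = FALSE)
  }
  prods <- vapply(steps, `[[`, "", "product")
  if (anyDuplicated(prods)) {
    stop("each species may be produced by at most one step", call. = FALSE)
  }
  structure(list(branches = branches), class = "pathway_graph")
}

#' Default two-branch C99 processing topology
#'
#' Returns the canonical pathway: the Abeta40 branch
#' (C99->Ab49->Ab46->Ab43->Ab40 with coproducts AICD50-99, ITL, VIV, IAT)
#' and the Abeta42 branch (C99->Ab48->Ab45->Ab42->Ab38 with coproducts
#' AICD49-99, VIT, TVI, VVIA).  AICD fragments are named by their C99
#' residue span.
#'
#' @return A `pathway_graph` with two branches of four steps each.
#' @examples
#' g <- default_pathway()
#' graph_steps(g)
#' @export
default_pathway <- function() {
  b40 <- list(
    list(precursor = "C99",  product = "Ab49", coproduct = "AICD50-99"),
    list(precursor = "Ab49", product = "Ab46", coproduct = "ITL", sequence = "ITL"),
    list(precursor = "Ab46", product = "Ab43", coproduct = "VIV", sequence = "VIV"),
    list(precursor = "Ab43", product = "Ab40", coproduct = "IAT", sequence = "IAT")
  )
  b42 <- list(
    list(precursor = "C99",  product = "Ab48", coproduct = "AICD49-99"),
    list(precursor = "Ab48", product = "Ab45", coproduct = "VIT", sequence = "VIT"),
    list(precursor = "Ab45", product = "Ab42", coproduct = "TVI", sequence = "TVI"),
    list(precursor = "Ab42", product = "Ab38", coproduct = "VVIA", sequence = "VVIA")
  )
  pathway_graph(list(Ab40 = b40, Ab42 = b42))
}

#' Flat step table of a pathway graph
#'
#' @param graph A `pathway_graph`.
#' @return A data.frame with one row per step: `branch`, `step`
#'   (identifier `"precursor->product"`), `precursor`, `product`,
#'   `coproduct`, `sequence` (NA for endoproteolysis), `index` (position
#'   within its branch, 1 = endoproteolysis), `terminal` (logical, step
#'   producing the branch-terminal species).
#' @export
graph_steps <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  bn <- names(graph$branches)
  if (is.null(bn)) bn <- paste0("branch", seq_along(graph$branches))
  rows <- list()
  for (b in seq_along(graph$branches)) {
    steps <- graph$branches[[b]]
    for (i in seq_along(steps)) {
      s <- steps[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        branch    = bn[b],
        step      = paste0(s$precursor, "->", s$product),
        precursor = s$precursor,
        product   = s$product,
        coproduct = s$coproduct,
        sequence  = if (is.null(s$sequence)) NA_character_ else s$sequence,
        index     = i,
        terminal  = i == length(steps),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Species and coproduct identifiers of a graph
#'
#' `graph_species()` lists the Abeta intermediate/product species (the
#' products of every step, in branch order); `graph_coproducts()` lists
#' the coproduct identifiers in the same order.
#'
#' @param graph A `pathway_graph`.
#' @return Character vector of identifiers.
#' @export
graph_species <- function(graph) graph_steps(graph)$product

#' @rdname graph_species
#' @export
graph_coproducts <- function(graph) graph_steps(graph)$coproduct

#' Read a pathway graph from a YAML config
#'
#' The config holds one entry per branch; each branch is a list of steps
#' with `precursor`, `product`, `coproduct` and optional `sequence`.  An
#' optional top-level `peptides` map (id -> sequence) is attached as the
#' `"peptides"` attribute.  The packaged default lives at
#' `system.file("extdata", "pathway.yaml", package = "procleave")`.
#'
#' @param path Path to a YAML file.
#' @return A `pathway_graph`.
#' @export
read_pathway <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$branches)) stop("pathway config needs a `branches` entry", call. = FALSE)
  g <- pathway_graph(cfg$branches)
  if (!is.null(cfg$peptides)) attr(g, "peptides") <- unlist(cfg$peptides)
  g
}

#' @export
print.pathway_graph <- function(x, ...) {
  st <- graph_steps(x)
  cat("<pathway_graph> ", length(x$branches), " branches, ",
      nrow(st), " steps\n", sep = "")
  for (b in unique(st$branch)) {
    sb <- st[st$branch == b, ]
    chain <- c(sb$precursor[1], sb$product)
    cat("  ", b, ": ", paste(chain, collapse = " -> "),
        "  [", paste(sb$coproduct, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}
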