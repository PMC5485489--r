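#' Build a protein interaction network from an edge table
#'
#' Constructs a simple undirected graph from a two-column table of protein
#' identifier pairs. Self-interactions are dropped and duplicate pairs (in
#' either orientation) are collapsed, so the result always satisfies the
#' simple-graph invariants assumed by every downstream index. Identifiers are
#' case-sensitive opaque strings; no symbol normalization is attempted.
#'
#' @param edges A data frame whose first two columns are protein identifiers
#'   (coerced to character). Further columns are ignored.
#' @param nodes Optional character vector of node identifiers to include even
#'   when isolated (e.g. proteins with no reported interaction).
#' @return An [igraph::igraph] object. The graph attribute `load_report` holds
#'   a one-row tibble counting dropped self-loops and duplicate pairs.
#' @examples
#' net <- protein_network(data.frame(a = c("A", "B", "C", "A"),
#'                                   b = c("B", "A", "C", "B")))
#' igraph::gsize(net)  # single A-B edge survives
#' @export
protein_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2 && nrow(edges) > 0) {
    abort("`edges` must have at least two columns of protein identifiers.")
  }
  if (nrow(edges) == 0) {
    from <- to <- character()
  } else {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
  }
  keep <- !is.na(from) & !is.na(to)
  from <- from[keep]
  to <- to[keep]
  self <- from == to
  n_self <- sum(self)
  from2 <- pmin(from[!self], to[!self])
  to2 <- pmax(from[!self], to[!self])
  key <- paste(from2, to2, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  all_nodes <- sort(unique(c(from, to, as.character(nodes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from2[!dup], to = to2[!dup]),
    directed = FALSE,
    vertices = if (length(all_nodes)) all_nodes else NULL
  )
  igraph::graph_attr(g, "load_report") <- tibble(
    n_input = length(keep), n_kept = igraph::gsize(g),
    n_self_loops = n_self, n_duplicates = n_dup, n_bad_lines = 0L
  )
  g
}

#' Read an interaction network from a delimited edge list
#'
#' Expects one interaction per line: two identifier fields separated by
#' `delimiter`. Lines starting with `#` are comments; lines with fewer than
#' two fields are skipped and counted in the load report.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Field separator (default tab).
#' @return An igraph network as from [protein_network()], with the skipped
#'   line count recorded in the `load_report` graph attribute.
#' @export
read_edge_list <- function(path, delimiter = "\t") {
  if (!file.exists(path)) abort(paste0("Cannot read edge list: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  ok <- vapply(parts, function(p) sum(nzchar(p)) >= 2, logical(1))
  n_bad <- sum(!ok)
  fields <- lapply(parts[ok], function(p) p[nzchar(p)][1:2])
  edges <- data.frame(
    from = vapply(fields, `[`, character(1), 1),
    to = vapply(fields, `[`, character(1), 2)
  )
  net <- protein_network(edges)
  rep <- igraph::graph_attr(net, "load_report")
  rep$n_bad_lines <- n_bad
  igraph::graph_attr(net, "load_report") <- rep
  net
}

#' Write a network as a two-column edge list
#'
#' @param net An igraph network.
#' @param path Output file path.
#' @param delimiter Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, delimiter = "\t") {
  el <- igraph::as_edgelist(net)
  writeLines(paste(el[, 1], el[, 2], sep = delimiter), path)
  invisible(path)
}

#' Extract the largest connected component
#'
#' Interaction data are incomplete, leaving isolated proteins and tiny
#' fragments; all analyses run on the maximal connected component. Ties in
#' component size are broken deterministically by the lexicographically
#' smallest member identifier.
#'
#' @param net An igraph network.
#' @return The induced subgraph on the largest component (empty network for
#'   an empty input).
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0) return(net)
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1) {
    nm <- igraph::V(net)$name
    mins <- vapply(best, function(k) min(nm[comp$membership == k]), character(1))
    best <- best[order(mins)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == best[1]))
}

#' Partition network proteins into targets and pending test sets
#'
#' Splits the node set into known drug targets `D`, pending test proteins
#' with chemical-physical properties `PT1`, and pending test proteins without
#' properties `PT2`. Identifiers absent from the network are dropped with a
#' count. The target ratio `DR = |D|/|P|` and pending ratio `PR = |PT|/|P|`
#' (with `P` the full node set) are computed from the realized sets.
#'
#' @param net An igraph network.
#' @param target_ids Character vector of known drug-target identifiers.
#' @param featured_ids Character vector of identifiers that have the
#'   chemical-physical property table (targets included or not; targets are
#'   always classed as targets).
#' @return A `labeled_proteome` object; see [tidy.labeled_proteome()] for the
#'   per-protein assignment table and [glance.labeled_proteome()] for counts
#'   and ratios.
#' @export
assign_labels <- function(net, target_ids, featured_ids = character()) {
  nodes <- igraph::V(net)$name
  target_ids <- unique(as.character(target_ids))
  featured_ids <- unique(as.character(featured_ids))
  d <- sort(intersect(target_ids, nodes))
  pt1 <- sort(setdiff(intersect(featured_ids, nodes), d))
  pt2 <- sort(setdiff(nodes, c(d, pt1)))
  if (length(d) == 0) {
    warn("No target identifiers matched the network; enrichment will be flagged.")
  }
  assignments <- tibble(
    protein = c(d, pt1, pt2),
    class = factor(
      rep(c("target", "pending_featured", "pending_unfeatured"),
          times = c(length(d), length(pt1), length(pt2))),
      levels = c("target", "pending_featured", "pending_unfeatured")
    )
  ) |> arrange(.data$protein)
  n_total <- length(nodes)
  structure(
    list(
      assignments = assignments,
      n_targets = length(d),
      n_pending_featured = length(pt1),
      n_pending_unfeatured = length(pt2),
      n_total = n_total,
      dr = if (n_total) length(d) / n_total else NA_real_,
      pr = if (n_total) (length(pt1) + length(pt2)) / n_total else NA_real_,
      dropped_targets = length(setdiff(target_ids, nodes)),
      dropped_featured = length(setdiff(featured_ids, nodes)),
      flagged = length(d) == 0
    ),
    class = "labeled_proteome"
  )
}

#' @export
print.labeled_proteome <- function(x, ...) {
  cat("<labeled_proteome>\n")
  cat(sprintf("  targets (D):              %d\n", x$n_targets))
  cat(sprintf("  pending, featured (PT1):  %d\n", x$n_pending_featured))
  cat(sprintf("  pending, unfeatured (PT2):%d\n", x$n_pending_unfeatured))
  cat(sprintf("  total (P): %d   DR = %.4f   PR = %.4f\n", x$n_total, x$dr, x$pr))
  if (x$dropped_targets || x$dropped_featured) {
    cat(sprintf("  dropped: %d target ids, %d featured ids not in network\n",
                x$dropped_targets, x$dropped_featured))
  }
  invisible(x)
}

#' @describeIn assign_labels Per-protein class assignments as a tibble.
#' @param x A `labeled_proteome`.
#' @param ... Unused.
#' @export
tidy.labeled_proteome <- function(x, ...) x$assignments

#' @describeIn assign_labels One-row tibble of counts and ratios.
#' @export
glance.labeled_proteome <- function(x, ...) {
  tibble(
    n_targets = x$n_targets, n_pending_featured = x$n_pending_featured,
    n_pending_unfeatured = x$n_pending_unfeatured, n_total = x$n_total,
    dr = x$dr, pr = x$pr,
    dropped_targets = x$dropped_targets, dropped_featured = x$dropped_featured
  )
}

# identifier sets D / PT1 / PT2 / PT as a named list (internal)
label_sets <- function(labels) {
  a <- labels$assignments
  list(
    D = a$protein[a$class == "target"],
    PT1 = a$protein[a$class == "pending_featured"],
    PT2 = a$protein[a$class == "pending_unfeatured"],
    PT = a$protein[a$class != "target"]
  )
}

#' Coverage accounting between original and used data
#'
#' For each category, reports how much of the originally collected data
#' survives preprocessing, as a percentage `used/original` rounded to one
#' decimal. A zero original count yields an undefined (NA) ratio.
#'
#' @param original Named numeric vector of originally collected counts.
#' @param used Named numeric vector of counts used in the analysis, with the
#'   same names; every `used` must not exceed its `original`.
#' @return A tibble with columns `category`, `original`, `used`,
#'   `coverage_pct`.
#' @examples
#' coverage_report(c(targets = 149, pt1 = 1212), c(targets = 138, pt1 = 1180))
#' @export
coverage_report <- function(original, used) {
  if (is.null(names(original))) names(original) <- as.character(seq_along(original))
  used <- used[names(original)]
  if (any(is.na(used))) abort("`used` must provide a count for every category in `original`.")
  if (any(used > original)) abort("`used` counts cannot exceed `original` counts.")
  tibble(
    category = names(original),
    original = as.numeric(original),
    used = as.numeric(used),
    coverage_pct = ifelse(original == 0, NA_real_, round(100 * used / original, 1))
  )
}

#' Read a label file (one identifier per line)
#'
#' @param path Path to the file; `#` lines are comments.
#' @return Character vector of identifiers.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("Cannot read label file: ", path))
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a chemical-physical property table
#'
#' Tab-separated with a header; first column is the protein identifier,
#' remaining columns numeric properties (39 in the reference data). Rows with
#' any missing value are rejected and reported via the `dropped` attribute.
#'
#' @param path Path to the TSV file.
#' @return A tibble with first column `protein` and numeric feature columns;
#'   attribute `dropped` is a tibble of rejected rows.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Cannot read feature table: ", path))
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tab)[1] <- "protein"
  tab$protein <- as.character(tab$protein)
  feat <- tab[-1]
  if (!all(vapply(feat, is.numeric, logical(1)))) {
    abort("All feature columns must be numeric.")
  }
  bad <- !stats::complete.cases(tab)
  out <- tab[!bad, ]
  attr(out, "dropped") <- tab[bad, ]
  if (any(bad)) {
    warn(sprintf("Dropped %d feature row(s) with missing values.", sum(bad)))
  }
  out
}

#' Remove a set of proteins from a network
#'
#' Returns the induced subgraph on the remaining nodes; edges incident to a
#' removed protein are dropped. Identifiers absent from the network are
#' ignored (their count is attached as attribute `n_missing`).
#'
#' @param net An igraph network.
#' @param ids Character vector of identifiers to delete.
#' @return The reduced igraph network.
#' @export
remove_nodes <- function(net, ids) {
  ids <- unique(as.character(ids))
  present <- intersect(ids, igraph::V(net)$name)
  out <- igraph::delete_vertices(net, present)
  attr(out, "n_missing") <- length(ids) - length(present)
  out
}
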