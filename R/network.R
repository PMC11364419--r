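#' Signed regulatory circuits
#'
#' A `reg_network` is a small directed, signed graph of transcription-factor
#' nodes. Edges carry a sign (`"activation"` or `"inhibition"`) and nodes an
#' optional functional role tag used only for annotation and plotting.
#' Node order is stable and defines the state-vector index used by the
#' simulation engine and all downstream matrices.
#'
#' @param edges A data frame with columns `source`, `target`, `sign`
#'   (`"activation"`/`"inhibition"`). One row per directed edge; at most one
#'   edge per ordered (source, target) pair; self-edges are allowed.
#' @param nodes Optional data frame with columns `name` and `role`
#'   (`"pigmentation"`, `"cell_cycle"` or `"unassigned"`). When omitted,
#'   nodes are taken from the edge list in first-appearance order (sources
#'   before targets, row by row) with role `"unassigned"`.
#'
#' @return A `reg_network` object: a list with tibbles `$nodes` (`name`,
#'   `role`) and `$edges` (`source`, `target`, `sign`).
#' @examples
#' toggle <- reg_network(tibble::tibble(
#'   source = c("A", "B"), target = c("B", "A"),
#'   sign = "inhibition"
#' ))
#' toggle
#' @export
reg_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0 && !all(c("source", "target", "sign") %in% names(edges))) {
    abort("`edges` must have columns source, target, sign")
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(source = character(), target = character(),
                            sign = character())
  }
  edges <- edges[, c("source", "target", "sign")]
  if (is.null(nodes)) {
    seen <- unique(as.vector(t(as.matrix(edges[, c("source", "target")]))))
    nodes <- tibble::tibble(name = seen, role = "unassigned")
  } else {
    nodes <- tibble::as_tibble(nodes)
    if (!"name" %in% names(nodes)) abort("`nodes` must have a `name` column")
    if (!"role" %in% names(nodes)) nodes$role <- "unassigned"
    nodes <- nodes[, c("name", "role")]
  }
  net <- structure(list(nodes = nodes, edges = edges), class = "reg_network")
  bad <- validate_network(net)
  if (length(bad) > 0) {
    abort(paste0("invalid network:\n", paste0("- ", bad, collapse = "\n")))
  }
  net
}

#' @export
print.reg_network <- function(x, ...) {
  cat(sprintf("<reg_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  cat("nodes:", paste(x$nodes$name, collapse = ", "), "\n")
  if (nrow(x$edges) > 0) {
    arrow <- ifelse(x$edges$sign == "activation", "->", "-|")
    cat("edges:", paste0(x$edges$source, " ", arrow, " ", x$edges$target,
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Node names of a regulatory network
#' @param net A [reg_network()].
#' @return Character vector of node names in index order.
#' @export
network_nodes <- function(net) net$nodes$name

#' Validate a regulatory network
#'
#' Checks the structural invariants of a circuit: non-empty unique node
#' names, edge endpoints that resolve to declared nodes, at most one edge
#' per ordered (source, target) pair, and recognised signs and roles.
#' Violations are returned as messages, not raised, so the function can be
#' used to audit hand-built or file-loaded circuits.
#'
#' @param net An object with `$nodes` and `$edges` tibbles (not necessarily
#'   a validated `reg_network`).
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_network <- function(net) {
  out <- character()
  nodes <- net$nodes
  edges <- net$edges
  if (any(!nzchar(nodes$name))) out <- c(out, "node with empty name")
  dup_nodes <- unique(nodes$name[duplicated(nodes$name)])
  for (d in dup_nodes) out <- c(out, sprintf("duplicate node name '%s'", d))
  bad_role <- setdiff(unique(nodes$role),
                      c("pigmentation", "cell_cycle", "unassigned"))
  for (r in bad_role) out <- c(out, sprintf("unknown node role '%s'", r))
  if (nrow(edges) > 0) {
    for (col in c("source", "target")) {
      missing <- setdiff(unique(edges[[col]]), nodes$name)
      for (m in missing) {
        out <- c(out, sprintf("edge %s '%s' is not a declared node", col, m))
      }
    }
    key <- paste(edges$source, edges$target, sep = "\r")
    dup <- unique(key[duplicated(key)])
    for (d in dup) {
      pair <- strsplit(d, "\r", fixed = TRUE)[[1]]
      out <- c(out, sprintf("duplicate edge %s -> %s", pair[1], pair[2]))
    }
    bad_sign <- setdiff(unique(edges$sign), c("activation", "inhibition"))
    for (s in bad_sign) out <- c(out, sprintf("unknown edge sign '%s'", s))
  }
  out
}

#' The packaged melanocyte pigmentation-proliferation circuit
#'
#' Returns the seven-node circuit coupling the pigmentation regulators MITF
#' and LEF1 (mutual activation) to the Rb-E2F cell-cycle entry switch (MYC,
#' E2F, RB, CycD, CycE), with reciprocal MITF-MYC inhibition closing the
#' antagonism between the pigmentation and proliferation programs and E2F
#' self-activation providing the bistable cell-cycle entry. The same circuit
#' ships as a `.topo` file under `inst/extdata/melanocyte.topo`.
#'
#' @return A [reg_network()] with roles tagged `pigmentation` for MITF and
#'   LEF1 and `cell_cycle` for the remaining five nodes.
#' @examples
#' net <- melanocyte_network()
#' network_nodes(net)
#' @export
melanocyte_network <- function() {
  path <- system.file("extdata", "melanocyte.topo", package = "melcircuit",
                      mustWork = TRUE)
  net <- read_topology(path)
  net$nodes$role <- ifelse(net$nodes$name %in% c("MITF", "LEF1"),
                           "pigmentation", "cell_cycle")
  net
}
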