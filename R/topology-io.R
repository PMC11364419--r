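#' Read a circuit from a `.topo` file
#'
#' The `.topo` dialect is the whitespace-delimited edge list used by
#' random-circuit-perturbation simulators: an optional header line
#' `Source Target Type` followed by one edge per line with type code `1`
#' for activation and `2` for inhibition. Nodes are created in
#' first-appearance order, which fixes the state-vector indexing for all
#' downstream stages.
#'
#' @param path Path to a `.topo` file.
#' @return A [reg_network()].
#' @examples
#' topo <- system.file("extdata", "melanocyte.topo", package = "melcircuit")
#' read_topology(topo)
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) abort(sprintf("topology file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[[ln]])
    if (!nzchar(raw)) next
    fields <- strsplit(raw, "[ \t]+")[[1]]
    if (ln == 1 && length(fields) == 3 &&
        all(tolower(fields) == c("source", "target", "type"))) next
    if (length(fields) != 3) {
      abort(sprintf("%s: line %d: expected 3 whitespace-separated fields, got %d",
                    path, ln, length(fields)))
    }
    if (!fields[3] %in% c("1", "2")) {
      abort(sprintf("%s: line %d: unknown type code '%s' (must be 1 or 2)",
                    path, ln, fields[3]))
    }
    rows[[length(rows) + 1]] <- fields
  }
  if (length(rows) == 0) {
    return(reg_network(tibble::tibble(source = character(),
                                      target = character(),
                                      sign = character())))
  }
  m <- do.call(rbind, rows)
  edges <- tibble::tibble(
    source = m[, 1],
    target = m[, 2],
    sign = c("activation", "inhibition")[as.integer(m[, 3])]
  )
  reg_network(edges)
}

#' Write a circuit to a `.topo` file
#'
#' Writes the standard header `Source Target Type` and one line per edge
#' (type `1` = activation, `2` = inhibition). Reading the file back with
#' [read_topology()] reproduces the signed edge set exactly; node order is
#' recovered as first appearance in the edge list.
#'
#' @param net A [reg_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(net, path) {
  stopifnot(inherits(net, "reg_network"))
  type <- ifelse(net$edges$sign == "activation", 1L, 2L)
  lines <- c("Source Target Type",
             if (nrow(net$edges) > 0)
               paste(net$edges$source, net$edges$target, type))
  tryCatch(writeLines(lines, path),
           error = function(e) abort(sprintf("cannot write '%s': %s", path,
                                             conditionMessage(e))))
  invisible(path)
}
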