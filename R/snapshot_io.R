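# Plain-text snapshot format: versioned header lines followed by one row
# per vertex.

#' Write a snapshot to a delimited text file
#'
#' Format: comment header (`# erythrosim snapshot v1`, time, domain) and a
#' tab-separated table with columns `cell_id`, `kind`, `rigid`, `k_bend`,
#' `A0`, `vertex_index`, `x`, `y` (coordinates wrapped into the domain).
#'
#' @param snap An `rbc_snapshot`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snap, path) {
  stopifnot(inherits(snap, "rbc_snapshot"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# erythrosim snapshot v1",
               sprintf("# time %.17g", snap$time),
               sprintf("# domain %.17g %.17g", snap$domain[1],
                       snap$domain[2])), con)
  tabs <- lapply(seq_along(snap$cells), function(i) {
    cl <- snap$cells[[i]]
    data.frame(cell_id = i, kind = cl$kind, rigid = cl$rigid,
               k_bend = cl$k_bend, A0 = cl$A0,
               vertex_index = seq_len(nrow(cl$vertices)),
               x = cl$vertices[, 1], y = cl$vertices[, 2])
  })
  utils::write.table(do.call(rbind, tabs), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a snapshot written by [write_snapshot()]
#'
#' @param path File path.
#' @return An `rbc_snapshot`.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, n = 3)
  if (!startsWith(lines[1], "# erythrosim snapshot v1")) {
    stop("not an erythrosim snapshot file (missing version header)")
  }
  time <- as.numeric(strsplit(lines[2], " ")[[1]][3])
  domain <- as.numeric(strsplit(lines[3], " ")[[1]][3:4])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  cells <- lapply(split(tab, tab$cell_id), function(g) {
    g <- g[order(g$vertex_index), , drop = FALSE]
    ring_cell(g$kind[1], cbind(g$x, g$y), g$A0[1],
              l0 = NA_real_, k_bend = g$k_bend[1], rigid = g$rigid[1])
  })
  snapshot(cells[order(as.integer(names(cells)))], domain, time = time)
}
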