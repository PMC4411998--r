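# SWC export/import for ground-truth architectures and CSV export for
# voxel skeletons. SWC type codes: 1 stem-seed, 2 lower primary, 3 lower
# secondary, 4 upper primary, 5 upper secondary.

.SWC_TYPE <- function(compartment, ord) {
  ifelse(compartment == "stem-seed", 1L,
  ifelse(compartment == "lower", ifelse(ord == "primary", 2L, 3L),
         ifelse(ord == "primary", 4L, 5L)))
}

#' Write an architecture (snapshot) as SWC
#'
#' @param tree an \linkS4class{ArchitectureTree}.
#' @param path output file.
#' @param week optional week; only nodes existing at that week are written.
#' @return \code{path}, invisibly.
#' @export
writeSWC <- function(tree, path, week = NULL) {
  nd <- if (is.null(week)) treeNodes(tree) else treeSnapshot(tree, week)
  swc <- data.frame(id = nd$id, type = .SWC_TYPE(nd$compartment, nd$order),
                    x = nd$x, y = nd$y, z = nd$z, radius = nd$radius,
                    parent = ifelse(is.na(nd$parent), -1L, nd$parent))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC export: positions in mm; type 1 stem-seed, 2/3 lower primary/secondary, 4/5 upper primary/secondary", con)
  utils::write.table(format(swc, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an SWC file as an architecture
#'
#' Week information is not part of SWC; all nodes get birth_week 1.
#'
#' @param path SWC file.
#' @return an \linkS4class{ArchitectureTree}.
#' @export
readSWC <- function(path) {
  raw <- utils::read.table(path, comment.char = "#",
                           col.names = c("id", "type", "x", "y", "z",
                                         "radius", "parent"))
  comp <- c("stem-seed", "lower", "lower", "upper", "upper")[raw$type]
  ord <- c("primary", "primary", "secondary", "primary", "secondary")[raw$type]
  nodes <- data.frame(id = raw$id, compartment = comp, order = ord,
                      x = raw$x, y = raw$y, z = raw$z, radius = raw$radius,
                      parent = ifelse(raw$parent < 0, NA_integer_,
                                      as.integer(raw$parent)),
                      birth_week = 1L)
  new("ArchitectureTree", nodes = nodes)
}

#' Write a skeleton as a sparse voxel CSV
#'
#' Columns: i, j, k (1-based voxel coordinates), compartment, order.
#'
#' @param skel a \linkS4class{SkeletonGraph}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
writeSkeletonCSV <- function(skel, path) {
  utils::write.csv(skeletonLabels(skel), path, row.names = FALSE)
  invisible(path)
}
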