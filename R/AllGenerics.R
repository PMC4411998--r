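#' @rdname VoxelGrid-class
#' @param x a \linkS4class{VoxelGrid}
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))

#' @rdname VoxelGrid-class
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridValues", "VoxelGrid", function(x) x@values)

#' @rdname VoxelGrid-class
#' @export
setMethod("gridDims", "VoxelGrid", function(x) dim(x@values))

#' @rdname VoxelGrid-class
#' @export
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)

#' @rdname ArchitectureTree-class
#' @param x an \linkS4class{ArchitectureTree}
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))

#' @rdname ArchitectureTree-class
#' @export
setMethod("treeNodes", "ArchitectureTree", function(x) x@nodes)

#' @rdname SkeletonGraph-class
#' @param x a \linkS4class{SkeletonGraph}
#' @export
setGeneric("skeletonCoords", function(x) standardGeneric("skeletonCoords"))

#' @rdname SkeletonGraph-class
#' @export
setMethod("skeletonCoords", "SkeletonGraph", function(x) x@coords)

#' @rdname SkeletonGraph-class
#' @export
setGeneric("skeletonLabels", function(x) standardGeneric("skeletonLabels"))

#' @rdname SkeletonGraph-class
#' @export
setMethod("skeletonLabels", "SkeletonGraph", function(x) {
  data.frame(i = x@coords[, 1], j = x@coords[, 2], k = x@coords[, 3],
             compartment = x@compartment, order = x@order)
})

#' Edge list of a skeleton under 26-connectivity
#'
#' @param x a \linkS4class{SkeletonGraph}
#' @return integer matrix with two columns of voxel row indices.
#' @export
setGeneric("skeletonEdges", function(x) standardGeneric("skeletonEdges"))

#' @rdname skeletonEdges
#' @export
setMethod("skeletonEdges", "SkeletonGraph", function(x) {
  if (nrow(x@coords) == 0L) return(matrix(integer(), 0, 2))
  cpp_adjacency_pairs(x@coords - 1L, as.integer(x@dims))
})

#' @rdname RootMask-class
#' @param x a \linkS4class{RootMask}
#' @export
setGeneric("maskLayers", function(x) standardGeneric("maskLayers"))

#' @rdname RootMask-class
#' @export
setMethod("maskLayers", "RootMask", function(x) x@layer)

#' @rdname FractalFit-class
#' @param x a \linkS4class{FractalFit}
#' @export
setGeneric("fractalDim", function(x) standardGeneric("fractalDim"))

#' @rdname FractalFit-class
#' @export
setMethod("fractalDim", "FractalFit", function(x) x@fd)
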