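#' Accessors
#'
#' Small accessor generics for the package's S4 containers, so user code
#' never reaches into slots.
#'
#' @param x an object.
#' @name accessors
NULL

#' @describeIn accessors the (H, W, c) probability array of a [ProbMap-class].
#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))
setMethod("probValues", "ProbMap", function(x) x@values)

#' @describeIn accessors the (H, W, c, T) array of an [MCStack-class].
#' @export
setGeneric("stackPasses", function(x) standardGeneric("stackPasses"))
setMethod("stackPasses", "MCStack", function(x) x@passes)

#' @describeIn accessors number of Monte-Carlo passes T.
#' @export
setGeneric("nPasses", function(x) standardGeneric("nPasses"))
setMethod("nPasses", "MCStack", function(x) dim(x@passes)[4])

#' @describeIn accessors integer label matrix of a [MaskImage-class].
#' @export
setGeneric("maskLabels", function(x) standardGeneric("maskLabels"))
setMethod("maskLabels", "MaskImage", function(x) x@labels)

#' @describeIn accessors number of pixel classes.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
setMethod("nClasses", "MaskImage", function(x) x@nClasses)
setMethod("nClasses", "ModelConfig", function(x) x@nClasses)
setMethod("nClasses", "SegDataset", function(x) x@nClasses)
setMethod("nClasses", "ProbMap", function(x) dim(x@values)[3])

#' @describeIn accessors image ids of a [SegDataset-class].
#' @export
setGeneric("datasetIds", function(x) standardGeneric("datasetIds"))
setMethod("datasetIds", "SegDataset", function(x) names(x@images))

#' @describeIn accessors images of a [SegDataset-class] (named list).
#' @export
setGeneric("datasetImages", function(x) standardGeneric("datasetImages"))
setMethod("datasetImages", "SegDataset", function(x) x@images)

#' @describeIn accessors masks of a [SegDataset-class] (named list).
#' @export
setGeneric("datasetMasks", function(x) standardGeneric("datasetMasks"))
setMethod("datasetMasks", "SegDataset", function(x) x@masks)

#' @describeIn accessors configuration of a [UNetModel-class].
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
setMethod("modelConfigOf", "UNetModel", function(x) x@config)

#' @describeIn accessors labelled ids of an [ALState-class].
#' @export
setGeneric("labeledIds", function(x) standardGeneric("labeledIds"))
setMethod("labeledIds", "ALState", function(x) x@labeledIds)

#' @describeIn accessors unlabelled pool ids of an [ALState-class].
#' @export
setGeneric("poolIds", function(x) standardGeneric("poolIds"))
setMethod("poolIds", "ALState", function(x) x@poolIds)

#' @describeIn accessors per-iteration history of an [ALState-class].
#' @export
setGeneric("alHistory", function(x) standardGeneric("alHistory"))
setMethod("alHistory", "ALState", function(x) x@history)

#' @describeIn accessors trained model of an [ALState-class].
#' @export
setGeneric("alModel", function(x) standardGeneric("alModel"))
setMethod("alModel", "ALState", function(x) x@model)

#' Subset a dataset by id
#'
#' @param x a [SegDataset-class].
#' @param ids character ids to keep (order preserved).
#' @return a [SegDataset-class] with the selected images (and their masks,
#'   where present).
#' @export
subsetDataset <- function(x, ids) {
  stopifnot(is(x, "SegDataset"))
  missing <- setdiff(ids, names(x@images))
  if (length(missing))
    stop("dataset has no image(s): ", paste(missing, collapse = ", "))
  new("SegDataset", images = x@images[ids],
      masks = x@masks[intersect(ids, names(x@masks))],
      nClasses = x@nClasses)
}
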