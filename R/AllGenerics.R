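#' @rdname PeakSet
#' @param object,x a PeakSet, PeakCollection or PromoterSet.
#' @export
setGeneric("peakSetName", function(object) standardGeneric("peakSetName"))
#' @rdname PeakSet
#' @export
setGeneric("tfId", function(object) standardGeneric("tfId"))
#' @rdname PeakSet
#' @export
setGeneric("tfFamily", function(object) standardGeneric("tfFamily"))
#' @rdname PeakSet
#' @export
setGeneric("sampleType", function(object) standardGeneric("sampleType"))
#' @rdname PeakSet
#' @export
setGeneric("frip", function(object) standardGeneric("frip"))
#' @rdname PeakSet
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @rdname PeakSet
#' @export
setGeneric("nPeaks", function(object) standardGeneric("nPeaks"))
#' @rdname PromoterSet-class
#' @param object a PromoterSet.
#' @export
setGeneric("promoterLength", function(object) standardGeneric("promoterLength"))
#' @rdname PromoterSet-class
#' @export
setGeneric("universe", function(object) standardGeneric("universe"))
#' @rdname PeakCollection
#' @export
setGeneric("versionLabel", function(object) standardGeneric("versionLabel"))

#' @rdname PeakSet
#' @export
setMethod("peakSetName", "PeakSet", function(object) object@name)
#' @rdname PeakSet
#' @export
setMethod("tfId", "PeakSet", function(object) object@tfId)
#' @rdname PeakSet
#' @export
setMethod("tfFamily", "PeakSet", function(object) object@tfFamily)
#' @rdname PeakSet
#' @export
setMethod("sampleType", "PeakSet", function(object) object@sampleType)
#' @rdname PeakSet
#' @export
setMethod("frip", "PeakSet", function(object) object@frip)
#' @rdname PeakSet
#' @export
setMethod("peaks", "PeakSet", function(object) object@peaks)
#' @rdname PeakSet
#' @export
setMethod("nPeaks", "PeakSet", function(object) length(object@peaks))

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet", object@name, "\n",
      " TF: ", object@tfId, " (", object@tfFamily, "), library: ",
      object@sampleType, "\n",
      " peaks: ", length(object@peaks),
      ", FRIP: ", ifelse(is.na(object@frip), "NA",
                         sprintf("%.4f", object@frip)), "\n", sep = "")
})

#' @rdname PeakCollection
#' @export
setMethod("versionLabel", "PeakCollection", function(object) object@versionLabel)
#' @rdname PeakCollection
#' @export
setMethod("length", "PeakCollection", function(x) length(x@peakSets))
#' @rdname PeakCollection
#' @export
setMethod("names", "PeakCollection", function(x) names(x@peakSets))

#' @rdname PeakCollection
#' @param i index or name of a member peak set.
#' @export
setMethod("[[", "PeakCollection", function(x, i) x@peakSets[[i]])

#' @rdname PeakCollection
#' @param j,drop,... ignored (list-style extraction).
#' @export
setMethod("[", "PeakCollection", function(x, i, j, ..., drop = FALSE) {
  PeakCollection(x@peakSets[i], versionLabel = x@versionLabel,
                 provenance = x@provenance)
})

setMethod("show", "PeakCollection", function(object) {
  n <- length(object@peakSets)
  cat("PeakCollection '", object@versionLabel, "' with ", n, " peak set",
      ifelse(n == 1, "", "s"), "\n", sep = "")
  if (n) {
    shown <- head(names(object@peakSets), 5L)
    cat(" ", paste(shown, collapse = ", "),
        if (n > 5L) ", ..." else "", "\n", sep = "")
  }
})

#' @rdname PromoterSet-class
#' @export
setMethod("promoterLength", "PromoterSet", function(object) object@upstreamLength)
#' @rdname PromoterSet-class
#' @export
setMethod("universe", "PromoterSet", function(object) names(object))

setMethod("show", "PromoterSet", function(object) {
  cat("PromoterSet: ", length(object), " promoters, L = ",
      object@upstreamLength, " bp upstream of the TSS\n", sep = "")
  methods::callNextMethod()
})

setMethod("show", "ReplicaBundle", function(object) {
  cat("ReplicaBundle: IDR-merged set with ", length(object@idr@peaks),
      " peaks, ", length(object@replicas), " replica(s)\n", sep = "")
})
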