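#' @title Accessors for g4slip containers
#' @description Small accessor generics so user code never touches slots
#'   directly.
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x, ...) standardGeneric("nAtoms"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x, ...) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x, ...) standardGeneric("frameTimes"))

#' @rdname accessors
#' @export
setGeneric("hills", function(x, ...) standardGeneric("hills"))

#' @rdname accessors
#' @export
setGeneric("nHills", function(x, ...) standardGeneric("nHills"))

#' @rdname accessors
#' @export
setGeneric("tetrads", function(x, ...) standardGeneric("tetrads"))

#' @rdname accessors
#' @export
setGeneric("triads", function(x, ...) standardGeneric("triads"))

#' @rdname accessors
#' @export
setGeneric("unpaired", function(x, ...) standardGeneric("unpaired"))

#' @rdname accessors
setMethod("atoms", "G4Structure", function(x, ...) x@atoms)

#' @rdname accessors
setMethod("coords", "G4Structure", function(x, ...) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname accessors
#' @param frame frame index.
setMethod("coords", "G4Trajectory", function(x, frame = NULL, ...) {
  if (is.null(frame)) return(x@coords)
  x@coords[, , frame, drop = TRUE]
})

#' @rdname accessors
setMethod("nAtoms", "G4Structure", function(x, ...) nrow(x@atoms))

#' @rdname accessors
setMethod("nAtoms", "G4Trajectory", function(x, ...) dim(x@coords)[1])

#' @rdname accessors
setMethod("atoms", "G4Trajectory", function(x, ...) x@topology@atoms)

#' @rdname accessors
setMethod("nFrames", "G4Trajectory", function(x, ...) dim(x@coords)[3])

#' @rdname accessors
setMethod("frameTimes", "G4Trajectory", function(x, ...) x@times)

#' @rdname accessors
setMethod("hills", "BiasState", function(x, ...) x@hills)

#' @rdname accessors
setMethod("nHills", "BiasState", function(x, ...) nrow(x@hills))

#' @rdname accessors
setMethod("tetrads", "TetradComposition", function(x, ...) x@tetrads)

#' @rdname accessors
setMethod("triads", "TetradComposition", function(x, ...) x@triads)

#' @rdname accessors
setMethod("unpaired", "TetradComposition", function(x, ...) x@unpaired)

#' Extract a single frame as a structure
#'
#' @param traj a [G4Trajectory-class].
#' @param i frame index.
#' @return a [G4Structure-class] with the topology's atoms at frame
#'   \code{i}'s coordinates.
#' @export
frameStructure <- function(traj, i) {
  stopifnot(is(traj, "G4Trajectory"))
  s <- traj@topology
  s@atoms[, c("x", "y", "z")] <- traj@coords[, , i]
  s
}

setMethod("show", "G4Structure", function(object) {
  a <- object@atoms
  cat("G4Structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resid))), "residues\n")
  if (nrow(a)) {
    rn <- table(a$resname)
    cat("  resnames:", paste(names(rn), rn, sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "G4Trajectory", function(object) {
  cat("G4Trajectory:", dim(object@coords)[3], "frames x",
      dim(object@coords)[1], "atoms; t =",
      min(object@times), "..", max(object@times), "ps\n")
})

setMethod("show", "BiasState", function(object) {
  cat("BiasState:", nrow(object@hills), "hills in", object@d, "CV(s)")
  if (length(object@gridNodes)) cat(" [grid cache attached]")
  cat("\n")
})

setMethod("show", "TetradComposition", function(object) {
  fmt <- function(v) paste0("{", paste0("G", v, collapse = ","), "}")
  cat("TetradComposition:\n")
  for (t in object@tetrads) cat("  tetrad", fmt(t), "\n")
  for (i in seq_along(object@triads))
    cat("  triad ", fmt(object@triads[[i]]), " at ",
        object@triadEnds[i], "\n", sep = "")
  if (length(object@unpaired))
    cat("  unpaired", fmt(object@unpaired), "\n")
})

setMethod("show", "SlipCode", function(object) {
  cat("SlipCode:", object@label)
  if (nrow(object@moves))
    cat(" (", paste0(object@moves$column, object@moves$dir,
                     collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "FESGrid", function(object) {
  cat("FESGrid over", paste(object@cvNames, collapse = " x "), ":",
      paste(dim(object@F), collapse = " x "), "bins;",
      sum(object@visited), "visited; range 0 ..",
      round(max(object@F, na.rm = TRUE), 3), "kJ/mol\n")
})

setMethod("show", "ModelPotential", function(object) {
  cat("ModelPotential:", object@id, "(", object@d, "CV )\n")
})
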