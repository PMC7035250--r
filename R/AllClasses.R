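## Central S4 containers.  Coordinates are stored in Angstrom throughout;
## energies in kJ/mol; times in ps.

#' Atomic structure
#'
#' An ordered table of atoms (PDB-style fields) plus an optional
#' orthorhombic box.  Coordinates are in Angstrom.
#'
#' @slot atoms data.frame with columns \code{serial}, \code{name},
#'   \code{element}, \code{resname}, \code{resid}, \code{chain},
#'   \code{x}, \code{y}, \code{z}.
#' @slot box numeric(3) box lengths in Angstrom, or \code{NA}.
#' @exportClass G4Structure
setClass("G4Structure",
  representation(atoms = "data.frame", box = "numeric"),
  prototype(box = rep(NA_real_, 3))
)

setValidity("G4Structure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (nrow(a) == 0) return(TRUE)
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
    return("atom positions must be finite")
  if (any(a$resid < 1)) return("residue numbers must be >= 1")
  if (any(!nzchar(a$name))) return("atom names must be non-empty")
  TRUE
})

#' Coordinate trajectory
#'
#' Ordered coordinate frames over a fixed topology.
#'
#' @slot topology a [G4Structure-class] describing the atoms.
#' @slot coords numeric array \code{n_atoms x 3 x n_frames}, Angstrom.
#' @slot times numeric vector of frame times in ps, strictly increasing.
#' @exportClass G4Trajectory
setClass("G4Trajectory",
  representation(topology = "G4Structure", coords = "array",
                 times = "numeric")
)

setValidity("G4Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3)
    return("coords must be an n_atoms x 3 x n_frames array")
  if (d[1] != nrow(object@topology@atoms))
    return("frame atom count differs from topology")
  if (d[3] != length(object@times))
    return("length(times) must equal the number of frames")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Rational switching function
#'
#' PLUMED-style rational switch
#' \eqn{s(r) = (1 - x^n) / (1 - x^m)} with \eqn{x = (r - d0)/r0},
#' evaluated at the removable singularity \eqn{x = 1} by its limit
#' \eqn{n/m}.  Used to turn interatomic distances into smooth,
#' differentiable contact counts.
#'
#' @slot r0 switching radius, Angstrom, > 0.
#' @slot d0 offset, Angstrom, >= 0; distances at or below d0 count as a
#'   full contact.
#' @slot n,m even integer exponents with \code{m > n}.
#' @exportClass SwitchingFunction
setClass("SwitchingFunction",
  representation(r0 = "numeric", d0 = "numeric", n = "integer",
                 m = "integer"),
  prototype(r0 = 1.0, d0 = 0.0, n = 6L, m = 12L)
)

setValidity("SwitchingFunction", function(object) {
  if (object@r0 <= 0) return("r0 must be > 0")
  if (object@d0 < 0) return("d0 must be >= 0")
  if (object@n < 2 || object@n %% 2 != 0) return("n must be even and >= 2")
  if (object@m <= object@n || object@m %% 2 != 0)
    return("m must be even and > n")
  TRUE
})

#' Collective-variable specification
#'
#' Defines one collective variable over a fixed topology: a coordination
#' CV (sum of switched donor-acceptor distances over an explicit pair
#' list), a pi-pi stacking CV (sum of switched ring-centroid distances
#' over listed ring pairs), or an RMSD CV (superposed RMSD of a subset
#' against reference coordinates).
#'
#' @slot name CV name, e.g. \code{"Hb_core_native"} or \code{"pipi_core"}.
#' @slot kind one of \code{"coordination"}, \code{"pipi"}, \code{"rmsd"}.
#' @slot pairs two-column integer matrix of (donor, acceptor) atom
#'   indices (coordination).
#' @slot ringGroups list of integer vectors of ring heavy-atom indices
#'   (pipi).
#' @slot ringPairs two-column integer matrix indexing \code{ringGroups}
#'   (pipi); only listed pairs are counted.
#' @slot refCoords n x 3 reference coordinate matrix (rmsd).
#' @slot refIndices integer atom indices evaluated against
#'   \code{refCoords} (rmsd).
#' @slot switch a [SwitchingFunction-class].
#' @exportClass CVSpec
setClass("CVSpec",
  representation(name = "character", kind = "character", pairs = "matrix",
                 ringGroups = "list", ringPairs = "matrix",
                 refCoords = "matrix", refIndices = "integer",
                 switch = "SwitchingFunction"),
  prototype(pairs = matrix(integer(), 0, 2), ringGroups = list(),
            ringPairs = matrix(integer(), 0, 2),
            refCoords = matrix(numeric(), 0, 3), refIndices = integer())
)

setValidity("CVSpec", function(object) {
  if (!object@kind %in% c("coordination", "pipi", "rmsd"))
    return("kind must be coordination, pipi or rmsd")
  if (object@kind == "coordination" && nrow(object@pairs) == 0)
    return("coordination CV needs a non-empty pair list")
  if (object@kind == "pipi") {
    if (length(object@ringGroups) < 2)
      return("pipi CV needs at least two ring groups")
    if (any(lengths(object@ringGroups) < 3))
      return("every ring group needs >= 3 atoms")
  }
  TRUE
})

#' Strand-slippage code
#'
#' Alphanumeric label for a vertically slipped topology of the parallel
#' G-quadruplex.  Digits name the G-triplets (strand columns, 5'->3')
#' that move; the letter gives the direction: \code{d} (down, towards
#' 3') or \code{u} (up, towards 5').  \code{"native"} carries no moves.
#'
#' @slot label e.g. \code{"native"}, \code{"2d"}, \code{"3u"}, \code{"24d"}.
#' @slot moves data.frame with columns \code{column} (1-4) and
#'   \code{dir} ("u"/"d").
#' @exportClass SlipCode
setClass("SlipCode",
  representation(label = "character", moves = "data.frame")
)

setValidity("SlipCode", function(object) {
  m <- object@moves
  if (nrow(m) == 0) return(TRUE)
  if (!all(c("column", "dir") %in% names(m)))
    return("moves needs columns 'column' and 'dir'")
  if (anyDuplicated(m$column)) return("at most one move per column")
  if (!all(m$dir %in% c("u", "d"))) return("dir must be 'u' or 'd'")
  if (!all(m$column %in% 1:4)) return("column must be in 1..4")
  TRUE
})

#' Tetrad/triad composition of a (possibly slipped) G-core
#'
#' Which guanine residues form the full G-tetrad planes, which form a
#' G-triad (three-membered plane left by a slipped strand), and which
#' are unpaired, for one topology.  Residue vectors are ordered by
#' strand column so cyclic Hoogsteen edges are well defined.
#'
#' @slot tetrads list of integer(4) residue vectors, plane order 5'->3'.
#' @slot triads list of integer(3) residue vectors.
#' @slot triadEnds character tag per triad: \code{"5'"} or \code{"3'"}.
#' @slot triadColumns list of integer(3): strand column of each triad
#'   member.
#' @slot unpaired integer vector of residues outside any plane.
#' @exportClass TetradComposition
setClass("TetradComposition",
  representation(tetrads = "list", triads = "list", triadEnds = "character",
                 triadColumns = "list", unpaired = "integer"),
  prototype(tetrads = list(), triads = list(), triadEnds = character(),
            triadColumns = list(), unpaired = integer())
)

setValidity("TetradComposition", function(object) {
  all_res <- c(unlist(object@tetrads), unlist(object@triads),
               object@unpaired)
  if (anyDuplicated(all_res)) return("residue sets must be disjoint")
  if (any(lengths(object@tetrads) != 4)) return("tetrads must have 4 members")
  if (any(lengths(object@triads) != 3)) return("triads must have 3 members")
  if (length(object@triads) != length(object@triadEnds))
    return("one end tag per triad")
  TRUE
})

#' Well-tempered metadynamics parameters
#'
#' @slot w0 initial Gaussian height, kJ/mol.
#' @slot pace deposition stride, ps.
#' @slot gamma bias factor (> 1); hill heights are damped by
#'   \eqn{\exp(-V/((\gamma - 1) k T))}.
#' @slot sigma per-CV Gaussian widths, CV units.
#' @slot kT thermal energy, kJ/mol (2.494 at 300 K).
#' @exportClass WTMetaDParams
setClass("WTMetaDParams",
  representation(w0 = "numeric", pace = "numeric", gamma = "numeric",
                 sigma = "numeric", kT = "numeric"),
  prototype(w0 = 2.48, pace = 1, gamma = 20, sigma = c(0.2, 0.5),
            kT = 2.494)
)

setValidity("WTMetaDParams", function(object) {
  if (object@w0 < 0) return("w0 must be >= 0 (0 disables deposition)")
  if (object@gamma <= 1) return("gamma must be > 1")
  if (any(object@sigma <= 0)) return("sigma must be > 0")
  if (object@pace <= 0) return("pace must be > 0")
  if (object@kT <= 0) return("kT must be > 0")
  TRUE
})

#' Metadynamics bias state
#'
#' The accumulated bias as an ordered list of deposited Gaussians, plus
#' an optional grid cache holding the summed bias at grid nodes.  The
#' cache is exact at its nodes up to the 6-sigma hill truncation
#' (well below 1e-6 kJ/mol for default heights).
#'
#' @slot d number of biased CVs.
#' @slot hills numeric matrix, one row per hill: time, d centers,
#'   d sigmas, height.
#' @slot gridNodes list of node-position vectors per CV (empty if no
#'   cache).
#' @slot gridValues numeric array of cached bias values at the nodes.
#' @exportClass BiasState
setClass("BiasState",
  representation(d = "integer", hills = "matrix", gridNodes = "list",
                 gridValues = "array"),
  prototype(d = 1L, hills = matrix(numeric(), 0, 4), gridNodes = list(),
            gridValues = array(numeric(), 0))
)

setValidity("BiasState", function(object) {
  h <- object@hills
  if (ncol(h) != 2 * object@d + 2)
    return("hills must have 2*d + 2 columns (time, centers, sigmas, height)")
  if (nrow(h) > 1 && any(diff(h[, 1]) <= 0))
    return("hills must be strictly time-ordered")
  if (nrow(h) > 0 && any(h[, ncol(h)] <= 0))
    return("hill heights must be > 0")
  TRUE
})

#' One-sided wall restraint on a collective variable
#'
#' Harmonic-style lower wall: zero on the allowed side
#' (\eqn{s \ge} threshold), \eqn{\kappa (threshold - s)^{exp}} below it.
#'
#' @slot cv index of the restrained CV.
#' @slot threshold wall position, CV units.
#' @slot side only \code{"lower"} is supported.
#' @slot kappa force constant, kJ/mol per CV-unit^exp.
#' @slot exp integer exponent >= 2.
#' @exportClass WallRestraint
setClass("WallRestraint",
  representation(cv = "integer", threshold = "numeric", side = "character",
                 kappa = "numeric", exp = "integer"),
  prototype(cv = 1L, side = "lower", kappa = 500, exp = 2L)
)

setValidity("WallRestraint", function(object) {
  if (object@side != "lower") return("only lower walls are supported")
  if (object@kappa < 0) return("kappa must be >= 0")
  if (object@exp < 2) return("exp must be >= 2")
  TRUE
})

#' Analytic model potential in CV space
#'
#' Desk-scale surrogate free-energy landscapes sampled by the Langevin
#' metadynamics engine: a harmonic well, an asymmetric 1D double well,
#' or a 2D three-basin surface mimicking a native basin (deep), a
#' transition-state basin (intermediate) and a slipped-ensemble basin
#' (high).
#'
#' @slot id one of \code{"harmonic"}, \code{"double_well_1d"},
#'   \code{"three_basin_2d"}.
#' @slot d dimensionality (1 or 2).
#' @slot params named list of numeric parameters.
#' @slot U function(s-matrix) -> potential values, kJ/mol.
#' @slot grad function(s-vector) -> gradient vector, kJ/mol per unit.
#' @slot cppId integer id understood by the compiled engine.
#' @slot cppParams numeric parameter vector for the compiled engine.
#' @exportClass ModelPotential
setClass("ModelPotential",
  representation(id = "character", d = "integer", params = "list",
                 U = "function", grad = "function", cppId = "integer",
                 cppParams = "numeric")
)

#' Gridded free-energy surface
#'
#' Free energy on a regular CV grid, referenced so the minimum over
#' visited bins is zero; unvisited bins are flagged and carry NA.
#'
#' @slot cvNames names of the grid CVs.
#' @slot mids list of bin-midpoint vectors per CV.
#' @slot F numeric array of free energies, kJ/mol (NA where unvisited).
#' @slot visited logical array marking bins with samples.
#' @slot kT thermal energy used, kJ/mol.
#' @exportClass FESGrid
setClass("FESGrid",
  representation(cvNames = "character", mids = "list", F = "array",
                 visited = "array", kT = "numeric")
)

setValidity("FESGrid", function(object) {
  if (any(dim(object@F) != dim(object@visited)))
    return("F and visited must have identical dimensions")
  v <- object@F[object@visited]
  if (length(v) && abs(min(v) - 0) > 1e-9)
    return("minimum over visited bins must be zero")
  if (any(is.finite(object@F[!object@visited])))
    return("unvisited bins must be NA, not numbers")
  TRUE
})
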