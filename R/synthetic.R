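## Synthetic inputs: idealised parallel G4 coordinates for the native
## and every slipped topology (with channel cations, open/closed triad
## variants, bridging waters and a chi-settable 5' adenine
## placeholder), noisy transition trajectories between topologies, and
## the analytic model potentials sampled by the metadynamics engine.
##
## The guanine template is the ideal nucleotide geometry of the
## chemical component dictionary (base heavy atoms plus C1'/O4' for the
## glycosidic torsion), oriented with the base plane in z = 0.  Tetrad
## placement is solved at run time: a rigid in-plane pose (rotation +
## offset) is optimised so that the four C4-symmetric copies realise
## the Hoogsteen heavy-atom distances (N1->O6, N2->N7 about 2.9 A), a
## physical O6 channel radius, and no steric clashes.

.dg_template_raw <- function() {
  m <- matrix(c(
     0.253, -0.471,  0.705,
     0.897, -0.345, -0.573,
    -0.068,  0.111, -1.575,
    -1.172,  0.877, -1.341,
    -1.804,  1.094, -2.458,
    -1.145,  0.482, -3.472,
    -1.361,  0.377, -4.866,
    -2.321,  0.914, -5.391,
    -0.473, -0.327, -5.601,
     0.593, -0.928, -5.003,
     1.474, -1.643, -5.774,
     0.804, -0.839, -3.709,
    -0.027, -0.152, -2.917), ncol = 3, byrow = TRUE)
  rownames(m) <- c("O4'", "C1'", "N9", "C8", "N7", "C5", "C6", "O6",
                   "N1", "C2", "N2", "N3", "C4")
  m
}

.g4_env <- new.env(parent = emptyenv())

## template oriented with base plane in z = 0, base centroid at origin
.dg_template <- function() {
  if (!is.null(.g4_env$tpl)) return(.g4_env$tpl)
  m <- .dg_template_raw()
  base <- 3:13
  ctr <- colMeans(m[base, ])
  X <- sweep(m, 2, ctr)
  sv <- svd(X[base, ])
  R <- t(sv$v)
  if (det(R) < 0) R[3, ] <- -R[3, ]
  X <- X %*% t(R)
  .g4_env$tpl <- X
  X
}

.Rz <- function(a) {
  matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

#' Geometry parameters of the idealised G4 builder
#'
#' @param rise plane separation along the axis, Angstrom (3.4).
#' @param twist helical twist per plane, degrees (30).
#' @param core_radius soft target for the guanine base-centroid radius,
#'   Angstrom; the Hoogsteen and channel constraints dominate, so the
#'   achieved radius is ~4.8.
#' @param hbond target Hoogsteen heavy-atom donor-acceptor distance,
#'   Angstrom (2.9).
#' @param o6_radius target O6 distance from the channel axis, Angstrom
#'   (2.5), which puts an inter-plane axial K+ within ~3.0 of all
#'   eight coordinating O6.
#' @param layout strand layout, default [defaultStrandLayout()].
#' @return list of class \code{G4GeometryParams}.
#' @export
g4GeometryParams <- function(rise = 3.4, twist = 30, core_radius = 5.5,
                             hbond = 2.9, o6_radius = 2.5,
                             layout = defaultStrandLayout()) {
  stopifnot(rise > 0)
  structure(list(rise = rise, twist = twist, core_radius = core_radius,
                 hbond = hbond, o6_radius = o6_radius, layout = layout),
            class = "G4GeometryParams")
}

## rigid in-plane pose (theta, tx, ty) of the template such that four
## C4 copies form an ideal Hoogsteen tetrad; deterministic refinement
## from a frozen starting pose
.tetrad_pose <- function(params) {
  key <- paste0("tetrad_", params$hbond, "_", params$o6_radius, "_",
                params$core_radius)
  if (!is.null(.g4_env[[key]])) return(.g4_env[[key]])
  X <- .dg_template()
  base <- 3:13
  place <- function(par)
    sweep(X %*% t(.Rz(par[1])), 2, c(par[2], par[3], 0), "+")
  obj <- function(par) {
    A <- place(par)
    B <- A %*% t(.Rz(pi / 2))
    d1 <- sqrt(sum((A["N1", ] - B["O6", ])^2))
    d2 <- sqrt(sum((A["N2", ] - B["N7", ])^2))
    r6 <- sqrt(sum(A["O6", 1:2]^2))
    rc <- sqrt(sum(colMeans(A[base, ])[1:2]^2))
    D <- as.matrix(dist(rbind(A, B)))[1:13, 14:26]
    dimnames(D) <- list(rownames(A), rownames(A))
    D["N1", "O6"] <- NA; D["N2", "N7"] <- NA
    D["N1", "N7"] <- NA; D["N2", "O6"] <- NA
    Copp <- A %*% t(.Rz(pi))
    ster <- sum(pmax(0, params$hbond - D)^2, na.rm = TRUE) +
      sum(pmax(0, params$hbond - as.matrix(dist(rbind(A, Copp)))[1:13, 14:26])^2)
    (d1 - params$hbond)^2 + (d2 - params$hbond)^2 +
      0.5 * (r6 - params$o6_radius)^2 +
      0.005 * (rc - params$core_radius)^2 + ster
  }
  o <- optim(c(2.507186, -4.046832, -2.511185), obj,
             method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-12))
  pose <- place(o$par)
  .g4_env[[key]] <- pose
  pose
}

## C3 pose realising the rearranged ("closed") triad: only the
## non-canonical N2->O6 contact between neighbours, canonical
## Hoogsteen distances pushed beyond H-bond range
.closed_triad_pose <- function(params) {
  key <- paste0("closed_", params$hbond)
  if (!is.null(.g4_env[[key]])) return(.g4_env[[key]])
  X <- .dg_template()
  place <- function(par)
    sweep(X %*% t(.Rz(par[1])), 2, c(par[2], par[3], 0), "+")
  obj <- function(par) {
    A <- place(par)
    B <- A %*% t(.Rz(2 * pi / 3))
    dn2o6 <- sqrt(sum((A["N2", ] - B["O6", ])^2))
    pen <- function(p, q) pmax(0, 4.2 - sqrt(sum((p - q)^2)))^2
    D <- as.matrix(dist(rbind(A, B)))[1:13, 14:26]
    dimnames(D) <- list(rownames(A), rownames(A))
    D["N2", "O6"] <- NA
    (dn2o6 - params$hbond)^2 +
      pen(A["N1", ], B["O6", ]) + pen(A["N2", ], B["N7", ]) +
      pen(B["N1", ], A["O6", ]) + pen(B["N2", ], A["N7", ]) +
      sum(pmax(0, params$hbond - D)^2, na.rm = TRUE)
  }
  o <- optim(c(3.537491, -2.525486, -4.021619), obj,
             method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-12))
  pose <- place(o$par)
  .g4_env[[key]] <- pose
  pose
}

## rotate point p about the axis through a with unit direction u
.rot_about_axis <- function(p, a, u, angle) {
  u <- u / sqrt(sum(u^2))
  v <- p - a
  a + v * cos(angle) + c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1]) * sin(angle) +
    u * sum(u * v) * (1 - cos(angle))
}

#' Build an idealised parallel G4 structure
#'
#' Places each core guanine on its plane according to
#' \code{applySlip(layout, code)}; guanines slipped past the core ends
#' continue the helix one rise beyond.  Channel K+ ions sit on the
#' axis between consecutive tetrad planes, and - for open-triad
#' variants - between the triad and its neighbouring tetrad (the
#' bipyramidal site).  Optional extras: the rearranged closed-triad
#' geometry (no triad cation), two bridging waters in the triad's
#' vacant site, and a 4-atom 5' adenine placeholder with a settable
#' glycosidic chi.
#'
#' @param code slip code (string or [SlipCode-class]); \code{"native"}
#'   for the three-tetrad stem.
#' @param params a [g4GeometryParams()] list.
#' @param cations include channel K+ (default TRUE).
#' @param triad_form \code{"open"} (canonical triad edges +
#'   coordinating cation), \code{"closed"} (rearranged edges, no triad
#'   cation) or \code{"none"} (no triad cation either).
#' @param waters add two bridging waters in the triad vacancy.
#' @param chi1 if non-NULL, add an A1 placeholder (O4', C1', N9, C4)
#'   with this glycosidic chi in degrees.
#' @return a [G4Structure-class].
#' @export
buildIdealG4 <- function(code = "native", params = g4GeometryParams(),
                         cations = TRUE,
                         triad_form = c("open", "closed", "none"),
                         waters = FALSE, chi1 = NULL) {
  triad_form <- match.arg(triad_form)
  code <- slipCode(code)
  layout <- params$layout
  comp <- applySlip(layout, code)
  pose <- .tetrad_pose(params)
  rise <- params$rise
  twist <- params$twist * pi / 180
  shift <- integer(length(layout))
  if (nrow(code@moves))
    shift[code@moves$column] <- ifelse(code@moves$dir == "d", 1L, -1L)

  closed <- triad_form == "closed" && length(comp@triads)
  closed_res <- if (closed) comp@triads[[1]] else integer()
  closed_pose <- if (closed) .closed_triad_pose(params)

  atom_rows <- list()
  serial <- 0L
  add_atoms <- function(m, names, resname, resid, element = NULL) {
    if (is.null(element)) element <- substr(names, 1, 1)
    n <- nrow(m)
    rows <- .new_atoms(serial + seq_len(n), names, element, resname,
                       resid, "A", m)
    serial <<- serial + n
    atom_rows[[length(atom_rows) + 1]] <<- rows
  }

  ## optional A1 placeholder above the 5' face near column 1
  if (!is.null(chi1)) {
    tpl <- .dg_template()[c("O4'", "C1'", "N9", "C4"), ]
    chi0 <- dihedralAngle(tpl[1, ], tpl[2, ], tpl[3, ], tpl[4, ])
    ax <- tpl["N9", ] - tpl["C1'", ]
    tpl["C4", ] <- .rot_about_axis(tpl["C4", ], tpl["C1'", ], ax,
                                   (chi0 - chi1) * pi / 180)
    m <- sweep(tpl %*% t(.Rz(-twist)), 2, c(0, 0, rise), "+")
    add_atoms(m, rownames(tpl), "DA", 1L)
  }

  ## core guanines, residue order
  res_info <- list()
  for (c in seq_along(layout)) for (j in 1:3) {
    r <- layout[[c]][j]
    res_info[[as.character(r)]] <- list(column = c, plane = j + shift[c])
  }
  for (r in sort(as.integer(names(res_info)))) {
    info <- res_info[[as.character(r)]]
    p <- info$plane
    if (r %in% closed_res) {
      slot <- which(sort(closed_res) == r) - 1
      rot <- .Rz((p - 1) * twist + slot * 2 * pi / 3)
      m <- sweep(closed_pose %*% t(rot), 2, c(0, 0, -(p - 1) * rise), "+")
    } else {
      rot <- .Rz((p - 1) * twist + (info$column - 1) * pi / 2)
      m <- sweep(pose %*% t(rot), 2, c(0, 0, -(p - 1) * rise), "+")
    }
    add_atoms(m, rownames(pose), "DG", as.integer(r))
  }

  ## channel cations
  if (cations) {
    planes_of <- function(kind)
      vapply(kind, function(t) {
        r <- t[1]; res_info[[as.character(r)]]$plane
      }, 0L)
    tp <- sort(planes_of(comp@tetrads))
    ksites <- numeric(0)
    for (i in seq_along(tp)[-1])
      if (tp[i] - tp[i - 1] == 1)
        ksites <- c(ksites, -(mean(tp[(i - 1):i]) - 1) * rise)
    if (triad_form == "open" && length(comp@triads)) {
      trp <- planes_of(comp@triads)
      for (q in trp) {
        adj <- tp[abs(tp - q) == 1]
        if (length(adj))
          ksites <- c(ksites, -(mean(c(q, adj[1])) - 1) * rise)
      }
    }
    if (length(ksites)) {
      for (i in seq_along(ksites))
        add_atoms(matrix(c(0, 0, ksites[i]), 1, 3), "K", "K",
                  100L + i, element = "K")
    }
  }

  ## bridging waters in the triad vacancy
  if (waters && length(comp@triads)) {
    tri <- comp@triads[[1]]; cols <- comp@triadColumns[[1]]
    gap <- setdiff(1:4, cols)[1]
    prev <- tri[cols == (if (gap == 1) 4 else gap - 1)]
    nxt <- tri[cols == (if (gap == 4) 1 else gap + 1)]
    tmp <- do.call(rbind, atom_rows)
    get <- function(r, nm)
      as.numeric(tmp[tmp$resid == r & tmp$name == nm, c("x", "y", "z")])
    ## two waters straddling the vacancy midpoint (above/below the
    ## triad plane), each within H-bond reach of both flanking guanines
    mid <- (get(prev, "N1") + get(nxt, "O6")) / 2
    w1 <- mid + c(0, 0, 0.8)
    w2 <- mid - c(0, 0, 0.8)
    add_atoms(rbind(w1, w2), c("O", "O"), "HOH", 200L)
    ## second water gets its own residue number
    tmp2 <- atom_rows[[length(atom_rows)]]
    tmp2$resid <- c(200L, 201L)
    atom_rows[[length(atom_rows)]] <- tmp2
  }

  G4Structure(do.call(rbind, atom_rows))
}

#' Noisy transition trajectory between slipped topologies
#'
#' Linearly interpolates the slipping column's atoms between
#' consecutive ideal endpoint structures (all other atoms fixed), then
#' adds i.i.d. Gaussian coordinate noise per frame.  Consecutive codes
#' must differ by exactly one move.  Structures are built without
#' cations or waters so every frame shares one topology.
#'
#' @param codes list/vector of slip codes visited in order.
#' @param frames_per_segment frames per leg (endpoints included once).
#' @param noise_sd Gaussian coordinate noise, Angstrom (default 0.3).
#' @param seed RNG seed for the noise.
#' @param params geometry parameters.
#' @param dt frame spacing, ps.
#' @return a [G4Trajectory-class].
#' @export
transitionTrajectory <- function(codes, frames_per_segment = 100,
                                 noise_sd = 0.3, seed = 1,
                                 params = g4GeometryParams(), dt = 1) {
  stopifnot(length(codes) >= 2)
  codes <- lapply(codes, slipCode)
  key <- function(cd) paste(sort(paste0(cd@moves$column, cd@moves$dir)),
                            collapse = "+")
  for (i in seq_along(codes)[-1]) {
    a <- strsplit(key(codes[[i - 1]]), "\\+")[[1]]
    b <- strsplit(key(codes[[i]]), "\\+")[[1]]
    a <- a[nzchar(a)]; b <- b[nzchar(b)]
    if (length(setdiff(a, b)) + length(setdiff(b, a)) != 1)
      stop("transitionTrajectory: codes ", codes[[i - 1]]@label, " and ",
           codes[[i]]@label, " are not adjacent (must differ by one move)",
           call. = FALSE)
  }
  structs <- lapply(codes, function(cd)
    buildIdealG4(cd, params, cations = FALSE, triad_form = "none"))
  topo <- structs[[1]]
  n <- nAtoms(topo)
  frames <- list()
  for (seg in seq_along(codes)[-1]) {
    A <- coords(structs[[seg - 1]]); B <- coords(structs[[seg]])
    lam <- seq(0, 1, length.out = frames_per_segment)
    if (seg > 2) lam <- lam[-1]
    for (l in lam)
      frames[[length(frames) + 1]] <- (1 - l) * A + l * B
  }
  arr <- array(unlist(frames), c(n, 3, length(frames)))
  if (noise_sd > 0) {
    set.seed(seed)
    arr <- arr + array(rnorm(length(arr), sd = noise_sd), dim(arr))
  }
  G4Trajectory(topo, arr, (seq_len(dim(arr)[3]) - 1) * dt)
}

#' Analytic model potentials for the metadynamics engine
#'
#' \describe{
#'   \item{harmonic}{\eqn{U = k s^2 / 2}; parameter \code{k}
#'     (kJ/mol/unit^2, default 10).}
#'   \item{double_well_1d}{\eqn{U = B (s^2 - 1)^2 + (a/2) s}: quartic
#'     double well with barrier \code{barrier} (default 15 kJ/mol) and
#'     well asymmetry \code{asymmetry} (default 3 kJ/mol, the
#'     right-hand well higher by about \code{a}).}
#'   \item{three_basin_2d}{three inverted Gaussians (deep native-like
#'     basin A, intermediate B, high slipped-ensemble C) plus a
#'     confining bowl.  Parameters: \code{levels} (basin energies
#'     relative to A, default \code{c(0, 8, 13)} kJ/mol), \code{depth}
#'     (depth of A below the flat background, default 18),
#'     \code{centers} (3 x 2, default (-2,0), (0,2), (2,0)),
#'     \code{width} (0.6), \code{bowl} (5 kJ/mol at
#'     \code{bowl_radius} 3.5).}
#' }
#'
#' The analytic free-energy accessor for these CV-space potentials is
#' the potential itself (up to a constant): use \code{potential@U} on
#' any grid.
#'
#' @param id potential name.
#' @param ... parameter overrides, see above.
#' @return a [ModelPotential-class].
#' @export
makeModelPotential <- function(id = c("harmonic", "double_well_1d",
                                      "three_basin_2d"), ...) {
  id <- match.arg(id)
  over <- list(...)
  if (id == "harmonic") {
    par <- utils::modifyList(list(k = 10), over)
    U <- function(s) 0.5 * par$k * as.matrix(s)[, 1]^2
    gr <- function(s) par$k * s[1]
    new("ModelPotential", id = id, d = 1L, params = par, U = U,
        grad = gr, cppId = 1L, cppParams = par$k)
  } else if (id == "double_well_1d") {
    par <- utils::modifyList(list(barrier = 15, asymmetry = 3), over)
    tilt <- par$asymmetry / 2
    U <- function(s) {
      x <- as.matrix(s)[, 1]
      par$barrier * (x^2 - 1)^2 + tilt * x
    }
    gr <- function(s) 4 * par$barrier * (s[1]^2 - 1) * s[1] + tilt
    new("ModelPotential", id = id, d = 1L, params = par, U = U,
        grad = gr, cppId = 2L, cppParams = c(par$barrier, tilt))
  } else {
    par <- utils::modifyList(
      list(levels = c(0, 8, 13), depth = 25,
           centers = matrix(c(-2, 0, 0, 2, 2, 0), 3, 2, byrow = TRUE),
           width = 0.6, bowl = 5, bowl_radius = 3.5), over)
    depths <- par$depth - par$levels
    stopifnot(all(depths > 0), nrow(par$centers) == length(par$levels))
    ## equal bottom curvature (width ~ sqrt(depth)) keeps the harmonic
    ## entropy of the basins equal, so basin free-energy gaps track the
    ## stated levels up to anharmonic/background corrections
    widths <- par$width * sqrt(depths / depths[1])
    U <- function(s) {
      s <- as.matrix(s)
      u <- par$bowl * ((s[, 1]^2 + s[, 2]^2) / par$bowl_radius^2)^3
      for (g in seq_along(depths)) {
        dx <- s[, 1] - par$centers[g, 1]
        dy <- s[, 2] - par$centers[g, 2]
        u <- u - depths[g] * exp(-(dx^2 + dy^2) / (2 * widths[g]^2))
      }
      u
    }
    gr <- function(s) {
      r2 <- (s[1]^2 + s[2]^2) / par$bowl_radius^2
      g <- 6 * par$bowl * r2^2 / par$bowl_radius^2 * s
      for (gg in seq_along(depths)) {
        dxy <- s - par$centers[gg, ]
        g <- g + depths[gg] *
          exp(-sum(dxy^2) / (2 * widths[gg]^2)) / widths[gg]^2 * dxy
      }
      g
    }
    par$widths <- widths
    cpp <- c(length(depths),
             as.numeric(t(cbind(depths, par$centers, widths))),
             par$bowl, par$bowl_radius)
    new("ModelPotential", id = id, d = 2L, params = par, U = U,
        grad = gr, cppId = 3L, cppParams = cpp)
  }
}

#' Free-energy difference between the two wells of a 1D potential
#'
#' \eqn{\Delta F = -kT [\ln Z_{right} - \ln Z_{left}]} by numerical
#' quadrature of \eqn{e^{-U/kT}} on either side of \code{split}.
#'
#' @param potential a 1D [ModelPotential-class].
#' @param kT thermal energy, kJ/mol.
#' @param split dividing point between the wells (default 0).
#' @param lim integration half-range.
#' @param n quadrature points per side.
#' @return \code{F_right - F_left} in kJ/mol.
#' @export
wellFreeEnergyGap <- function(potential, kT = 2.494, split = 0,
                              lim = 3, n = 20001) {
  stopifnot(potential@d == 1)
  trap <- function(a, b) {
    x <- seq(a, b, length.out = n)
    y <- exp(-potential@U(matrix(x, ncol = 1)) / kT)
    sum((y[-1] + y[-n]) / 2) * (x[2] - x[1])
  }
  -kT * (log(trap(split, lim)) - log(trap(-lim, split)))
}

#' Free energies of rectangular basins of a 2D potential by quadrature
#'
#' @param potential a 2D [ModelPotential-class].
#' @param basins named list of rectangles (lo/hi), as for
#'   [assignBasins()].
#' @param kT thermal energy, kJ/mol.
#' @param n grid points per axis.
#' @return named numeric vector of free energies referenced to the
#'   deepest basin.
#' @export
basinQuadrature <- function(potential, basins, kT = 2.494, n = 401) {
  stopifnot(potential@d == 2)
  Fb <- vapply(basins, function(b) {
    x <- seq(b$lo[1], b$hi[1], length.out = n)
    y <- seq(b$lo[2], b$hi[2], length.out = n)
    g <- as.matrix(expand.grid(x, y))
    w <- exp(-potential@U(g) / kT)
    -kT * log(sum(w) * (x[2] - x[1]) * (y[2] - y[1]))
  }, 0.0)
  Fb - min(Fb)
}
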