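## Intercellular scale: DKK1 -> Wnt signal integration (with the
## anti-DKK1 antibody BHQ880) and the ranked stochastic choice of
## migration / division sites.

#' Effective DKK1 concentration under BHQ880
#'
#' \code{D^2 / (D + B)}: reduces to \code{D} when no antibody is present
#' and decreases monotonically with the BHQ880 dose \code{B}.
#'
#' @param D local DKK1 concentration (>= 0).
#' @param B local BHQ880 concentration (>= 0).
#' @return effective concentration (0 when \code{D = 0}).
#' @export
effectiveDkk1 <- function(D, B) {
  if (any(D < 0) || any(B < 0)) stop("concentrations must be >= 0")
  ifelse(D > 0, D^2 / (D + B), 0)
}

#' Effective Wnt signal at a site
#'
#' \code{E0 + beta_w / (1 + (D_e/K_D)^2)}: maximal Wnt activity without
#' DKK1, falling to the basal level \code{E0} as DKK1 saturates.
#'
#' @param De effective DKK1 concentration (>= 0).
#' @param params parameter list.
#' @return Wnt signal in \code{[E0, E0 + beta_w]}.
#' @export
wntEffect <- function(De, params) {
  if (any(De < 0)) stop("effective DKK1 must be >= 0")
  params$E0 + params$beta_w / (1 + (De / params$K_D)^2)
}

#' OPG:RANKL concentration ratio
#'
#' Guarded ratio \code{opg / max(rankl, epsilon)} so the OC
#' proliferation response stays finite when RANKL vanishes.
#'
#' @param opg,rankl local concentrations (>= 0).
#' @param epsilon positive guard (default 1e-9).
#' @return finite ratio >= 0.
#' @export
opgRanklRatio <- function(opg, rankl, epsilon = 1e-9) {
  if (any(opg < 0) || any(rankl < 0)) stop("concentrations must be >= 0")
  opg / pmax(rankl, epsilon)
}

#' Gaussian-type migration kernel
#'
#' \code{p(r) = exp(-r^2 / (4 pi D dt)) / (4 pi D dt)}, a strictly
#' decreasing relative weight in the distance \code{r}; the prefactor is
#' kept as printed in the source model since the site ranking normalizes
#' the weights anyway.
#'
#' @param r distance in lattice units (>= 0).
#' @param D_mot motility scale (distance squared over time, > 0).
#' @param dt step length in hours (> 0).
#' @return kernel weight.
#' @export
migrationKernel <- function(r, D_mot, dt) {
  if (any(r < 0)) stop("r must be >= 0")
  if (D_mot <= 0 || dt <= 0) stop("D_mot and dt must be > 0")
  s <- 4 * pi * D_mot * dt
  exp(-r^2 / s) / s
}

#' Neighborhood-preference weight
#'
#' Cells prefer lightly populated sites and avoid both isolation and
#' crowding: 0 neighbors -> 1/16; 1-2 -> 1; 3-4 -> 1/4; 5-6 -> 1/8.
#'
#' @param occupiedCount integer(s) in 0..6.
#' @return weight(s).
#' @export
neighborhoodPreference <- function(occupiedCount) {
  if (any(occupiedCount < 0 | occupiedCount > 6))
    stop("occupied count must be in 0..6")
  c(1 / 16, 1, 1, 1 / 4, 1 / 4, 1 / 8, 1 / 8)[occupiedCount + 1L]
}

#' Rank candidate sites and build the roulette partition
#'
#' Raw score per candidate: \code{R_l = (1/4) p(r_l) V_l} with the
#' migration kernel \code{p} and neighborhood preference \code{V};
#' normalized scores partition \[0, 1) into half-open intervals.
#'
#' @param origin integer triple, the cell's current site.
#' @param candidates integer matrix (rows = empty in-bounds sites).
#' @param occupancy occupancy array or [TumorState-class].
#' @param params parameter list (uses \code{D_mot}, \code{dt}).
#' @return list with \code{R} (raw), \code{Rnorm} (normalized, sums to
#'   1), and \code{breaks} (cumulative edges, length nrow + 1, last = 1).
#' @export
siteRanking <- function(origin, candidates, occupancy, params) {
  if (is(occupancy, "TumorState")) occupancy <- occupancy@occupancy
  n <- nrow(candidates)
  r <- sqrt(rowSums(sweep(candidates, 2L, as.numeric(origin))^2))
  v <- vapply(seq_len(n), function(l)
    neighborhoodPreference(countOccupiedNeighbors(candidates[l, ],
                                                  occupancy)), 0)
  R <- 0.25 * migrationKernel(r, params$D_mot, params$dt) * v
  tot <- sum(R)
  Rn <- if (tot > 0) R / tot else rep(0, n)
  list(R = R, Rnorm = Rn, breaks = c(0, cumsum(Rn)))
}

#' Select a migration / division site by roulette
#'
#' Ranks the empty candidate sites with [siteRanking()] and returns the
#' candidate whose half-open interval of the cumulative partition
#' contains the uniform draw \code{u}; \code{NULL} when no candidate
#' exists (the caller sets the cell reversibly quiescent).
#'
#' @inheritParams siteRanking
#' @param u uniform draw in \[0, 1).
#' @return integer triple of the chosen site, or \code{NULL}.
#' @export
rankAndSelect <- function(origin, candidates, occupancy, params,
                          u = stats::runif(1)) {
  if (is.null(candidates) || NROW(candidates) == 0L) return(NULL)
  if (u < 0 || u >= 1) stop("u must be in [0,1)")
  rk <- siteRanking(origin, candidates, occupancy, params)
  if (sum(rk$R) <= 0) return(NULL)  # guard; Eq-12 weights are positive
  l <- findInterval(u, rk$breaks, rightmost.closed = FALSE,
                    left.open = FALSE)
  candidates[min(l, nrow(candidates)), ]
}

## ---- engine fast paths --------------------------------------------------
## Inline versions used by the per-agent core: all candidates are face
## neighbors (r = 1), so the kernel factor cancels and only the
## neighborhood preference differentiates sites.

.VTAB <- c(1 / 16, 1, 1, 1 / 4, 1 / 4, 1 / 8, 1 / 8)

## Choose an empty face neighbor of agent `id` by the ranked-roulette
## rule; returns c(i,j,k,linearIndex) or NULL.
.selectEmptyNeighbor <- function(e, id) {
  d <- e$dims
  i <- e$i[id]; j <- e$j[id]; k <- e$k[id]
  cand <- integer(6); ci <- integer(6); cj <- integer(6); ck <- integer(6)
  n <- 0L
  if (i < d[1] && e$occ[li <- .linIndex(i + 1L, j, k, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i + 1L; cj[n] <- j; ck[n] <- k }
  if (i > 1L && e$occ[li <- .linIndex(i - 1L, j, k, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i - 1L; cj[n] <- j; ck[n] <- k }
  if (j < d[2] && e$occ[li <- .linIndex(i, j + 1L, k, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i; cj[n] <- j + 1L; ck[n] <- k }
  if (j > 1L && e$occ[li <- .linIndex(i, j - 1L, k, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i; cj[n] <- j - 1L; ck[n] <- k }
  if (k < d[3] && e$occ[li <- .linIndex(i, j, k + 1L, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i; cj[n] <- j; ck[n] <- k + 1L }
  if (k > 1L && e$occ[li <- .linIndex(i, j, k - 1L, d)] == 0L) {
    n <- n + 1L; cand[n] <- li; ci[n] <- i; cj[n] <- j; ck[n] <- k - 1L }
  if (n == 0L) return(NULL)
  w <- numeric(n)
  for (l in seq_len(n))
    w[l] <- .VTAB[.countOccupiedFast(e, ci[l], cj[l], ck[l]) + 1L]
  u <- stats::runif(1) * sum(w)
  acc <- 0
  for (l in seq_len(n)) {
    acc <- acc + w[l]
    if (u < acc) return(c(ci[l], cj[l], ck[l], cand[l]))
  }
  c(ci[n], cj[n], ck[n], cand[n])
}

.countOccupiedFast <- function(e, i, j, k) {
  d <- e$dims
  n <- 0L
  if (i < d[1] && e$occ[.linIndex(i + 1L, j, k, d)] != 0L) n <- n + 1L
  if (i > 1L   && e$occ[.linIndex(i - 1L, j, k, d)] != 0L) n <- n + 1L
  if (j < d[2] && e$occ[.linIndex(i, j + 1L, k, d)] != 0L) n <- n + 1L
  if (j > 1L   && e$occ[.linIndex(i, j - 1L, k, d)] != 0L) n <- n + 1L
  if (k < d[3] && e$occ[.linIndex(i, j, k + 1L, d)] != 0L) n <- n + 1L
  if (k > 1L   && e$occ[.linIndex(i, j, k - 1L, d)] != 0L) n <- n + 1L
  n
}

.migrateAgent <- function(e, id) {
  site <- .selectEmptyNeighbor(e, id)
  if (is.null(site)) return(FALSE)
  .setIntInPlace(e$occ, .linIndex(e$i[id], e$j[id], e$k[id], e$dims), 0L)
  .setIntInPlace(e$occ, site[4L], id)
  e$i[id] <- site[1L]; e$j[id] <- site[2L]; e$k[id] <- site[3L]
  if (e$phase[id] == 0L) e$phen[id] <- 1L
  TRUE
}

.spawnDaughter <- function(e, id, site) {
  nid <- e$n + 1L
  if (nid > length(e$type)) .growStorage(e, length(e$type))
  e$n <- nid
  e$type[nid] <- e$type[id]
  e$i[nid] <- site[1L]; e$j[nid] <- site[2L]; e$k[nid] <- site[3L]
  e$age[nid] <- 0
  e$phen[nid] <- 3L                       # daughter starts quiescent
  e$phase[nid] <- 0L; e$phaseStep[nid] <- 0L; e$cd[nid] <- 0L
  e$rest[nid] <- e$restlen[e$type[id]]    # post-mitotic rest
  e$alive[nid] <- TRUE
  .setIntInPlace(e$occ, site[4L], nid)
  invisible(nid)
}
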