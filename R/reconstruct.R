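# Inverse reconstruction of integer 2x2 contingency cells from published
# summary statistics.
#
# Published disproportionality tables often print a drug's event count `a`
# together with rounded summary statistics (PRR or ROR, a 95% CI, and a
# chi-square) but not the remaining cells b, c, d. Because the statistics
# are smooth invertible functions of the cells, the printed values confine
# the integer cells to a small feasible set; these routines enumerate that
# set exactly and return its most central member, which makes the printed
# table usable as a validation oracle for the forward statistics.
#
# The statistics pin down b, c, d with very different strength: the CI width
# mostly constrains 1/b + 1/c (+1/d), the ratio ties d to b*c, and the
# chi-square closes the system. Rounding of the printed values therefore
# leaves a thin curved sliver of feasible integer tables; any single member
# reproduces the supplied statistics at printed precision, while the
# centroid is the natural point estimate for held-out quantities.

# forward statistics, vectorized over any cell argument
recon_forward <- function(a, b, c, d, yates = TRUE, z = 1.96) {
  # cell products overflow integer storage; work in doubles throughout
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  chi2 <- n * dev^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  ror <- (a * d) / (b * c)
  prr <- (a / (a + b)) / (c / (c + d))
  se_ror <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  se_prr <- sqrt(pmax(0, 1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)))
  list(prr = prr, ror = ror, chi2 = chi2,
       ror_l = ror * exp(-z * se_ror), ror_u = ror * exp(z * se_ror),
       prr_l = prr * exp(-z * se_prr), prr_u = prr * exp(z * se_prr))
}

# targets/tolerances bundle for one reconstruction problem
recon_problem <- function(a, kind, point, ci, chi2, tol, z = 1.96) {
  stopifnot(kind %in% c("ror", "prr"), length(ci) == 2, ci[1] < ci[2])
  default_tol <- c(point = 0.005, lower = 0.005, upper = 0.005, chi2 = 0.005)
  if (!is.null(tol)) default_tol[names(tol)] <- tol
  gm <- sqrt(ci[1] * ci[2])
  if (abs(gm - point) / point > 0.02) {
    warning(sprintf(
      "point estimate %.4g is not the geometric mean of the CI bounds (%.4g); inputs may be inconsistent",
      point, gm), call. = FALSE)
  }
  list(a = a, kind = kind, point = point, lower = ci[1], upper = ci[2],
       chi2 = chi2, tol = default_tol, z = z,
       se2 = (log(ci[2] / ci[1]) / (2 * z))^2)
}

# the exact point+SE manifold parametrized by c: cells (b, c, d) or NA
recon_curve_at <- function(prob, cs) {
  a <- prob$a; pt <- prob$point; se2 <- prob$se2
  if (prob$kind == "ror") {
    rhs <- se2 - 1 / a - 1 / cs
    b <- ifelse(rhs > 0, (1 + a / (pt * cs)) / rhs, NA_real_)
    d <- pt * b * cs / a
  } else {
    lhs <- 1 / a + 1 / cs - se2
    B <- ifelse(lhs > 0, (1 + a / (pt * cs)) / lhs, NA_real_)
    b <- B - a
    d <- pt * B * cs / a - cs
    b[!is.na(b) & b <= 0] <- NA_real_
    d[!is.na(d) & d <= 0] <- NA_real_
  }
  list(b = b, c = cs, d = d, valid = !is.na(b) & !is.na(d) & b > 0 & d > 0)
}

# continuous anchors: points on the manifold where the chi-square residual
# crosses zero (every crossing is a candidate feasible branch). The SE
# implied by the printed CI carries the bounds' rounding noise, so the
# manifold is traced for the nominal SE and for the extremes the rounding
# slack allows; with no crossing anywhere, the minimum-residual point is
# the fallback
recon_anchors <- function(prob, yates) {
  cs <- exp(seq(log(max(prob$a / 50, 0.5)), log(1e9), length.out = 4000))
  se2_of <- function(lo, up) (log(up / lo) / (2 * prob$z))^2
  tl <- prob$tol[["lower"]]; tu <- prob$tol[["upper"]]
  se2s <- unique(c(prob$se2,
                   se2_of(prob$lower + tl, prob$upper - tu),
                   se2_of(prob$lower - tl, prob$upper + tu)))
  anchors <- list()
  fallback <- NULL; fallback_resid <- Inf
  for (se2 in se2s) {
    p2 <- prob; p2$se2 <- se2
    cv <- recon_curve_at(p2, cs)
    if (!any(cv$valid)) next
    b <- cv$b[cv$valid]; cc <- cv$c[cv$valid]; d <- cv$d[cv$valid]
    resid <- recon_forward(prob$a, b, cc, d, yates, prob$z)$chi2 - prob$chi2
    cross <- which(diff(sign(resid)) != 0)
    for (i in utils::head(cross, 4)) {
      root <- stats::uniroot(function(x) {
        p <- recon_curve_at(p2, x)
        recon_forward(prob$a, p$b, x, p$d, yates, prob$z)$chi2 - prob$chi2
      }, c(cc[i], cc[i + 1]), tol = 1e-9)$root
      p <- recon_curve_at(p2, root)
      anchors <- c(anchors, list(list(b = p$b, c = p$c, d = p$d)))
    }
    j <- which.min(abs(resid))
    if (abs(resid[j]) < fallback_resid) {
      fallback <- list(b = b[j], c = cc[j], d = d[j])
      fallback_resid <- abs(resid[j])
    }
  }
  # fine 2-D sweep over (SE, c): for weakly identified tables the chi-square
  # is nearly constant along each manifold and only an intermediate SE value
  # reaches the target
  se2_grid <- seq(min(se2s), max(se2s), length.out = 25)
  cs2 <- exp(seq(log(max(prob$a / 50, 0.5)), log(1e8), length.out = 300))
  for (se2 in se2_grid) {
    p2 <- prob; p2$se2 <- se2
    cv <- recon_curve_at(p2, cs2)
    if (!any(cv$valid)) next
    b <- cv$b[cv$valid]; cc <- cv$c[cv$valid]; d <- cv$d[cv$valid]
    resid <- recon_forward(prob$a, b, cc, d, yates, prob$z)$chi2 - prob$chi2
    j <- which.min(abs(resid))
    if (abs(resid[j]) < fallback_resid) {
      fallback <- list(b = b[j], c = cc[j], d = d[j])
      fallback_resid <- abs(resid[j])
    }
  }
  if (is.null(fallback) && !length(anchors)) {
    stop("no contingency table is compatible with the supplied CI; check the bounds",
         call. = FALSE)
  }
  # the minimum-residual point seeds a branch of its own: crossings can all
  # be degenerate (far tails of the manifold) while the feasible integer set
  # sits near the best non-crossing approach
  if (!is.null(fallback)) anchors <- c(anchors, list(fallback))
  # drop near-duplicate anchors (same branch found from two SE variants)
  kept <- list()
  for (an in anchors) {
    dup <- any(vapply(kept, function(k) {
      abs(log(k$c / an$c)) < 0.2 && abs(log(k$b / an$b)) < 0.2
    }, logical(1)))
    if (!dup) kept <- c(kept, list(an))
  }
  utils::head(kept, 5)
}

# per-c feasible d-windows for an integer vector b; returns intersected
# interval [lo, hi] per element via linearization of each constraint in d
recon_windows <- function(prob, yates, b, c) {
  a <- prob$a; tol <- prob$tol
  if (prob$kind == "ror") {
    dmid <- prob$point * b * c / a
    hw <- tol[["point"]] * b * c / a
  } else {
    dmid <- prob$point * (a + b) * c / a - c
    hw <- tol[["point"]] * (a + b) * c / a
  }
  lo <- pmax(dmid - hw, 1)
  hi <- dmid + hw
  bad <- !is.finite(dmid) | hi < 1
  dmid[bad] <- 1
  dmid <- pmax(dmid, 1)
  h <- pmax(dmid * 1e-4, 0.25)
  st0 <- recon_forward(a, b, c, dmid, yates, prob$z)
  stp <- recon_forward(a, b, c, dmid + h, yates, prob$z)
  stm <- recon_forward(a, b, c, pmax(dmid - h, dmid / 2), yates, prob$z)
  hm <- dmid - pmax(dmid - h, dmid / 2)
  keyL <- paste0(prob$kind, "_l"); keyU <- paste0(prob$kind, "_u")
  for (cons in list(c(keyL, "lower"), c(keyU, "upper"), c("chi2", "chi2"))) {
    v <- st0[[cons[1]]]; target <- prob[[cons[2]]]; tl <- tol[[cons[2]]]
    s <- (stp[[cons[1]]] - stm[[cons[1]]]) / (h + hm)
    undef <- !is.finite(v) | !is.finite(s)
    flat <- !undef & abs(s) < 1e-300
    d1 <- dmid + (target - tl - v) / s
    d2 <- dmid + (target + tl - v) / s
    wlo <- pmin(d1, d2); whi <- pmax(d1, d2)
    # flat constraint: feasible everywhere or nowhere; undefined: nowhere
    wlo[flat] <- ifelse(abs(v[flat] - target) <= tl, -Inf, Inf)
    whi[flat] <- ifelse(abs(v[flat] - target) <= tl, Inf, -Inf)
    wlo[undef] <- Inf; whi[undef] <- -Inf
    lo <- pmax(lo, wlo); hi <- pmin(hi, whi)
  }
  lo[bad] <- 2; hi[bad] <- 1
  list(lo = lo, hi = hi)
}

recon_check <- function(prob, yates, b, c, d) {
  st <- recon_forward(prob$a, b, c, d, yates, prob$z)
  pt_key <- prob$kind
  abs(st[[pt_key]] - prob$point) <= prob$tol[["point"]] &
    abs(st[[paste0(prob$kind, "_l")]] - prob$lower) <= prob$tol[["lower"]] &
    abs(st[[paste0(prob$kind, "_u")]] - prob$upper) <= prob$tol[["upper"]] &
    abs(st$chi2 - prob$chi2) <= prob$tol[["chi2"]]
}

# b-values of `rect` at column c, minus any parts covered by earlier
# rectangles (keeps a union of boxes free of double counting)
rect_bs_at <- function(rect, exclude, cc) {
  if (cc < rect$c[1] || cc > rect$c[2]) return(integer(0))
  bs <- seq(rect$b[1], rect$b[2])
  for (ex in exclude) {
    if (cc >= ex$c[1] && cc <= ex$c[2]) {
      bs <- bs[bs < ex$b[1] | bs > ex$b[2]]
    }
  }
  bs
}

# enumerate the feasible set over one (b, c) rectangle (minus overlap with
# earlier rectangles); accumulate centroid sums and feasible ranges
recon_enumerate <- function(prob, yates, rect, exclude = list()) {
  held_key <- if (prob$kind == "ror") "prr" else "ror"
  acc <- list(mass = 0, sb = 0, sc = 0, sd = 0, sheld = 0,
              b_min = Inf, b_max = -Inf, c_min = Inf, c_max = -Inf,
              held_min = Inf, held_max = -Inf)
  for (cc in seq(rect$c[1], rect$c[2])) {
    bs <- rect_bs_at(rect, exclude, cc)
    if (!length(bs)) next
    w <- recon_windows(prob, yates, bs, cc)
    lo <- ceiling(w$lo); hi <- floor(w$hi)
    nd <- pmax(0, hi - lo + 1)
    sel <- which(nd > 0)
    if (!length(sel)) next
    dmid <- (lo[sel] + hi[sel]) / 2
    st <- recon_forward(prob$a, bs[sel], cc, dmid, yates, prob$z)
    held <- st[[held_key]]
    he <- recon_forward(prob$a, bs[sel], cc, lo[sel], yates, prob$z)[[held_key]]
    hf <- recon_forward(prob$a, bs[sel], cc, hi[sel], yates, prob$z)[[held_key]]
    acc$mass <- acc$mass + sum(nd[sel])
    acc$sb <- acc$sb + sum(bs[sel] * nd[sel])
    acc$sc <- acc$sc + cc * sum(nd[sel])
    acc$sd <- acc$sd + sum(dmid * nd[sel])
    acc$sheld <- acc$sheld + sum(held * nd[sel])
    acc$b_min <- min(acc$b_min, bs[sel]); acc$b_max <- max(acc$b_max, bs[sel])
    acc$c_min <- min(acc$c_min, cc); acc$c_max <- max(acc$c_max, cc)
    acc$held_min <- min(acc$held_min, he, hf)
    acc$held_max <- max(acc$held_max, he, hf)
  }
  acc
}

# worst residual (in tolerance units) of a candidate, for diagnostics
recon_miss <- function(prob, yates, b, c, d) {
  st <- recon_forward(prob$a, b, c, d, yates, prob$z)
  r <- c(point = st[[prob$kind]] - prob$point,
         lower = st[[paste0(prob$kind, "_l")]] - prob$lower,
         upper = st[[paste0(prob$kind, "_u")]] - prob$upper,
         chi2 = st$chi2 - prob$chi2)
  max(abs(r) / prob$tol[names(r)])
}

# run one correction variant end to end; NULL if infeasible (or if the
# candidate region is degenerate and too large to enumerate)
recon_run_variant <- function(prob, yates, max_expand = 6) {
  anchors <- recon_anchors(prob, yates)
  mk_rect <- function(b0, c0) {
    list(b = c(max(1, floor(b0 * 0.55)), ceiling(b0 * 1.8)),
         c = c(max(1, floor(c0 * 0.7)), ceiling(c0 * 1.4)))
  }
  rects <- lapply(anchors, function(an) mk_rect(an$b, an$c))
  # ROR, its CI and the chi-square are all invariant under table
  # transposition (b <-> c), so for ror-kind problems every branch has a
  # mirror branch that must be enumerated too
  if (prob$kind == "ror") {
    mirrors <- lapply(anchors, function(an) mk_rect(an$c, an$b))
    rects <- c(rects, mirrors)
  }
  # cap the enumeration effort: a rect that wants to grow past these limits
  # is clamped (centred on where it stood) and the result flagged truncated,
  # since a weakly identified problem can have an effectively unbounded
  # feasible sliver
  clamp_rect <- function(r, b_cap = 5e4, c_cap = 2e4, cell_cap = 1e7) {
    clamped <- FALSE
    for (dim in c("b", "c")) {
      cap <- if (dim == "b") b_cap else c_cap
      if (diff(r[[dim]]) > cap) {
        mid <- mean(r[[dim]])
        r[[dim]] <- c(max(1, floor(mid - cap / 2)), ceiling(mid + cap / 2))
        clamped <- TRUE
      }
    }
    if (diff(r$b) * diff(r$c) > cell_cap) {
      cap <- floor(cell_cap / diff(r$b))
      mid <- mean(r$c)
      r$c <- c(max(1, floor(mid - cap / 2)), ceiling(mid + cap / 2))
      clamped <- TRUE
    }
    r$clamped <- clamped
    r
  }
  truncated <- FALSE
  for (k in seq_along(rects)) {
    rects[[k]] <- clamp_rect(rects[[k]])
    truncated <- truncated || rects[[k]]$clamped
  }
  accs <- vector("list", length(rects))
  stale <- rep(TRUE, length(rects))
  for (round in seq_len(max_expand)) {
    grew <- FALSE
    for (k in seq_along(rects)) {
      rk <- rects[[k]]
      if (stale[k]) {
        accs[[k]] <- recon_enumerate(prob, yates, rk, exclude = rects[seq_len(k - 1)])
        stale[k] <- FALSE
      }
      ak <- accs[[k]]
      if (ak$mass == 0) next
      if (ak$b_min <= rk$b[1] + 1 && rk$b[1] > 1) {
        rects[[k]]$b[1] <- max(1, floor(rk$b[1] * 0.7))
      }
      if (ak$b_max >= rk$b[2] - 1) rects[[k]]$b[2] <- ceiling(rk$b[2] * 1.4)
      if (ak$c_min <= rk$c[1] + 1 && rk$c[1] > 1) {
        rects[[k]]$c[1] <- max(1, floor(rk$c[1] * 0.7))
      }
      if (ak$c_max >= rk$c[2] - 1) rects[[k]]$c[2] <- ceiling(rk$c[2] * 1.4)
      rects[[k]] <- clamp_rect(rects[[k]])
      if (rects[[k]]$clamped) truncated <- TRUE
      # re-enumerate only when the (clamped) rectangle actually moved
      if (!identical(rects[[k]]$b, rk$b) || !identical(rects[[k]]$c, rk$c)) {
        stale[k] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  if (grew) truncated <- TRUE
  live <- accs[vapply(accs, function(a) a$mass > 0, logical(1))]
  if (!length(live)) return(NULL)
  acc <- Reduce(function(x, y) {
    list(mass = x$mass + y$mass, sb = x$sb + y$sb, sc = x$sc + y$sc,
         sd = x$sd + y$sd, sheld = x$sheld + y$sheld,
         b_min = min(x$b_min, y$b_min), b_max = max(x$b_max, y$b_max),
         c_min = min(x$c_min, y$c_min), c_max = max(x$c_max, y$c_max),
         held_min = min(x$held_min, y$held_min),
         held_max = max(x$held_max, y$held_max))
  }, live)
  centroid <- c(b = acc$sb, c = acc$sc, d = acc$sd) / acc$mass
  # pick the feasible integer member nearest the centroid
  best <- NULL; best_dist <- Inf
  for (k in seq_along(rects)) {
    for (cc in seq(rects[[k]]$c[1], rects[[k]]$c[2])) {
      bs <- rect_bs_at(rects[[k]], rects[seq_len(k - 1)], cc)
      if (!length(bs)) next
      w <- recon_windows(prob, yates, bs, cc)
      lo <- ceiling(w$lo); hi <- floor(w$hi)
      sel <- which(hi >= lo)
      if (!length(sel)) next
      dd <- pmin(pmax(round(centroid[["d"]]), lo[sel]), hi[sel])
      okx <- recon_check(prob, yates, bs[sel], cc, dd)
      sel <- sel[okx]; dd <- dd[okx]
      if (!length(sel)) next
      dist <- ((bs[sel] - centroid[["b"]]) / centroid[["b"]])^2 +
        ((cc - centroid[["c"]]) / centroid[["c"]])^2 +
        ((dd - centroid[["d"]]) / centroid[["d"]])^2
      i <- which.min(dist)
      if (dist[i] < best_dist) {
        best_dist <- dist[i]
        best <- c(b = bs[sel][i], c = cc, d = dd[i])
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(cells = best, acc = acc, centroid = centroid, yates = yates,
       truncated = truncated,
       miss = recon_miss(prob, yates, best[["b"]], best[["c"]], best[["d"]]))
}

#' Reconstruct an integer 2x2 table from published summary statistics
#'
#' Given the event-with-drug count `a` and three published statistics (a PRR
#' or ROR point estimate, its two-sided 95% CI, and a chi-square), finds
#' integer cells `b`, `c`, `d` whose forward statistics reproduce every
#' supplied value to its printed precision. The full feasible set of integer
#' tables is enumerated and the member closest to its centroid is returned;
#' the spread of the set (including the range of the held-out statistic) is
#' reported in the diagnostics, since rounded inputs determine the held-out
#' value only up to that spread. Both chi-square variants are tried under
#' `chi2_correction = "auto"` and the one admitting a feasible table is used.
#'
#' For `kind = "ror"` the supplied statistics are all invariant under table
#' transposition (swapping `b` and `c`), so the feasible set contains a
#' mirror branch and the held-out PRR is determined only up to that
#' two-branch ambiguity; [reconstruct_table_set()] resolves it when several
#' tables share one database snapshot.
#'
#' @param a event-with-drug cell count (fixed).
#' @param point published PRR or ROR point estimate.
#' @param ci numeric length-2, the published 95% CI of `point`.
#' @param chi2 published chi-square.
#' @param kind `"ror"` or `"prr"`: which statistic `point`/`ci` refer to.
#' @param tol named numeric overriding the default half-unit-in-last-printed-
#'   decimal tolerances `c(point=.005, lower=.005, upper=.005, chi2=.005)`
#'   (e.g. `c(chi2 = 5e-4)` when the chi-square is printed to 3 decimals).
#' @param chi2_correction `"auto"` (default), `"pearson"` or `"yates"`.
#' @param z normal quantile used for the CI, default 1.96.
#' @return a list with `table` (a [contingency_table()]), `stats` (forward
#'   [signal_stats()] on it, using the selected chi-square variant),
#'   `chi2_correction` (`"pearson"` or `"yates"`), and `diagnostics`
#'   (feasible mass, cell ranges, held-out statistic range, worst residual
#'   of the returned member in tolerance units).
#' @export
#' @examples
#' t0 <- contingency_table(12, 988, 40, 39000)
#' st <- signal_stats(t0)
#' r <- reconstruct_table(12, point = round(st$ror, 2),
#'                        ci = round(c(st$ror_l95, st$ror_u95), 2),
#'                        chi2 = round(st$chi2, 2), kind = "ror")
#' r$table
reconstruct_table <- function(a, point, ci, chi2, kind = c("ror", "prr"),
                              tol = NULL,
                              chi2_correction = c("auto", "pearson", "yates"),
                              z = 1.96) {
  kind <- match.arg(kind)
  chi2_correction <- match.arg(chi2_correction)
  prob <- recon_problem(a, kind, point, ci, chi2, tol, z)
  variants <- switch(chi2_correction,
                     auto = c(FALSE, TRUE),
                     pearson = FALSE,
                     yates = TRUE)
  runs <- lapply(variants, function(y) recon_run_variant(prob, y))
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    # diagnostic: best near-miss on the exact point+SE manifold
    anchor <- recon_anchors(prob, variants[1])[[1]]
    cand <- vapply(anchor, round, 0)
    stop(sprintf(
      paste0("no integer table reproduces the supplied statistics at printed ",
             "precision; best candidate b=%.0f c=%.0f d=%.0f misses by %.2f ",
             "tolerance units"),
      cand[["b"]], cand[["c"]], cand[["d"]],
      recon_miss(prob, variants[1], cand[["b"]], cand[["c"]], cand[["d"]])),
      call. = FALSE)
  }
  runs <- runs[ok]
  variants <- variants[ok]
  pick <- which.min(vapply(runs, function(r) r$miss, 0))
  run <- runs[[pick]]
  tab <- contingency_table(a, run$cells[["b"]], run$cells[["c"]], run$cells[["d"]])
  list(
    table = tab,
    stats = signal_stats(tab, yates = run$yates),
    chi2_correction = if (run$yates) "yates" else "pearson",
    diagnostics = list(
      feasible_mass = run$acc$mass,
      b_range = c(run$acc$b_min, run$acc$b_max),
      c_range = c(run$acc$c_min, run$acc$c_max),
      held_out_range = c(run$acc$held_min, run$acc$held_max),
      worst_residual = run$miss,
      truncated = run$truncated
    )
  )
}

#' Jointly reconstruct several drugs' tables from one reporting database
#'
#' When the published tables all come from a single snapshot of the same
#' spontaneous-report database, the drugs share two totals: the overall
#' report count `N = a+b+c+d` and the overall event count `a+c` (assuming no
#' report mentions two of the studied drugs, a safe approximation for rare
#' co-prescription). These shared constraints shrink the per-drug feasible
#' sets dramatically - often to a single configuration - so held-out
#' statistics are recovered far more precisely than by per-drug
#' reconstruction.
#'
#' @param specs named list; each element a list with fields `a`, `kind`,
#'   `point`, `ci`, `chi2` and optionally `tol`, as in [reconstruct_table()].
#' @param chi2_correction,z as in [reconstruct_table()].
#' @return a list with `tables` (named list of [contingency_table()]),
#'   `stats` (tibble of forward [signal_stats()], one row per drug),
#'   `event_total` (shared a+c), `grand_total` (shared N), and `feasible_mass`
#'   (number of joint integer configurations; 1 means uniquely determined).
#' @export
reconstruct_table_set <- function(specs,
                                  chi2_correction = c("auto", "pearson", "yates"),
                                  z = 1.96) {
  chi2_correction <- match.arg(chi2_correction)
  stopifnot(length(specs) >= 2, !is.null(names(specs)))
  # per-drug passes fix each drug's correction variant and b/c ranges
  singles <- lapply(specs, function(s) {
    reconstruct_table(s$a, s$point, s$ci, s$chi2, kind = s$kind,
                      tol = s$tol, chi2_correction = chi2_correction, z = z)
  })
  probs <- lapply(specs, function(s)
    recon_problem(s$a, s$kind, s$point, s$ci, s$chi2, s$tol, z))
  yates <- vapply(singles, function(r) r$chi2_correction == "yates", logical(1))
  t_ranges <- lapply(names(specs), function(nm) {
    specs[[nm]]$a + singles[[nm]]$diagnostics$c_range
  })
  t_lo <- max(vapply(t_ranges, `[`, 0, 1))
  t_hi <- min(vapply(t_ranges, `[`, 0, 2))
  if (t_lo > t_hi) {
    stop("no shared event total is compatible with all drugs' statistics",
         call. = FALSE)
  }
  b_ranges <- lapply(singles, function(r) {
    c(max(1, floor(r$diagnostics$b_range[1] * 0.95)),
      ceiling(r$diagnostics$b_range[2] * 1.05))
  })
  # pivot: drug with the smallest feasible mass yields the fewest N windows
  pivot <- names(specs)[which.min(vapply(singles, function(r)
    r$diagnostics$feasible_mass, 0))]
  others <- setdiff(names(specs), pivot)

  feas_b_at <- function(nm, Tt, N) {
    a <- specs[[nm]]$a
    cc <- Tt - a
    if (cc < 1) return(integer(0))
    bs <- seq(b_ranges[[nm]][1], b_ranges[[nm]][2])
    dd <- N - a - bs - cc
    keep <- dd >= 1
    bs <- bs[keep]; dd <- dd[keep]
    if (!length(bs)) return(integer(0))
    bs[recon_check(probs[[nm]], yates[[nm]], bs, cc, dd)]
  }

  mass <- 0
  sums <- lapply(specs, function(s) list(b = 0, w = 0))
  best <- NULL; best_w <- -1
  for (Tt in seq(t_lo, t_hi)) {
    a_p <- specs[[pivot]]$a
    cc <- Tt - a_p
    if (cc < 1) next
    bs <- seq(b_ranges[[pivot]][1], b_ranges[[pivot]][2])
    w <- recon_windows(probs[[pivot]], yates[[pivot]], bs, cc)
    lo <- ceiling(w$lo); hi <- floor(w$hi)
    sel <- which(hi >= lo)
    if (!length(sel)) next
    n_lo <- a_p + bs[sel] + cc + lo[sel]
    n_hi <- a_p + bs[sel] + cc + hi[sel]
    Ns <- sort(unique(unlist(Map(seq, n_lo, n_hi))))
    for (N in Ns) {
      fb <- lapply(setNames(names(specs), names(specs)),
                   function(nm) feas_b_at(nm, Tt, N))
      k <- vapply(fb, length, 0L)
      if (any(k == 0)) next
      wgt <- prod(k)
      mass <- mass + wgt
      for (nm in names(specs)) {
        sums[[nm]]$b <- sums[[nm]]$b + wgt * mean(fb[[nm]])
        sums[[nm]]$w <- sums[[nm]]$w + wgt
      }
      if (wgt > best_w) {
        best <- list(Tt = Tt, N = N, fb = fb)
        best_w <- wgt
      }
    }
  }
  if (mass == 0) {
    stop("no joint configuration reproduces every drug's statistics; ",
         "the tables may not come from one database snapshot", call. = FALSE)
  }
  tables <- lapply(setNames(names(specs), names(specs)), function(nm) {
    bbar <- sums[[nm]]$b / sums[[nm]]$w
    bsel <- best$fb[[nm]][which.min(abs(best$fb[[nm]] - bbar))]
    a <- specs[[nm]]$a
    contingency_table(a, bsel, best$Tt - a, best$N - a - bsel - (best$Tt - a))
  })
  stats <- dplyr::bind_rows(lapply(names(specs), function(nm) {
    dplyr::bind_cols(tibble(drug = nm),
                     signal_stats(tables[[nm]], yates = yates[[nm]]))
  }))
  list(tables = tables, stats = stats,
       event_total = best$Tt, grand_total = best$N, feasible_mass = mass)
}
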