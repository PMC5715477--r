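# Internal linear-programming kernel.
#
# Bounded-variable two-phase primal simplex for problems of the form
#   minimize  c'x   subject to  A x = b,  lb <= x <= ub
# with finite lower bounds and possibly infinite upper bounds.  Upper
# bounds are handled by the classical variable-complement technique, so
# every nonbasic variable sits at zero in working coordinates.  Dantzig
# pricing with a permanent switch to Bland's rule after a stall guards
# against cycling on the (highly degenerate) flux-balance LPs this
# package produces.

.LP_FEAS_TOL <- 1e-9   # feasibility / reduced-cost tolerance
.LP_PIV_TOL  <- 1e-9   # minimum pivot magnitude considered nonzero

#' @noRd
.lpSolve <- function(obj, A, rhs, lb, ub, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)))
    stop("internal LP requires finite lower bounds")
  if (any(lb > ub + 1e-7))
    return(list(status = "infeasible", x = rep(NA_real_, n),
                objval = NA_real_))

  ## shift to y = x - lb, y in [0, u]
  u  <- ub - lb
  u[u < 0] <- 0
  b0 <- rhs - as.vector(A %*% lb)

  ## orient rows so the initial artificial basis is feasible
  sgn <- ifelse(b0 < 0, -1, 1)
  N   <- n + m                      # structural + artificial columns
  Tb  <- cbind(A * sgn, diag(m))    # working tableau (B^-1 [A I])
  r   <- b0 * sgn                   # current basic values
  basis <- n + seq_len(m)
  comp  <- rep(FALSE, n)            # complemented (x' = u - x) flags
  uA    <- c(u, rep(Inf, m))

  objW  <- obj                      # working costs, sign-flipped on complement
  phase <- 1L
  cc    <- c(rep(0, n), rep(1, m))
  bland <- FALSE; stall <- 0L; lastz <- Inf
  it <- 0L
  status <- NULL

  repeat {
    it <- it + 1L
    if (it > maxit) { status <- "error"; break }

    zB <- cc[basis]
    d  <- cc - as.vector(zB %*% Tb)
    d[basis] <- 0
    cand <- which(d < -.LP_FEAS_TOL & uA > .LP_PIV_TOL)
    if (phase == 2L && length(cand)) cand <- cand[cand <= n]

    if (!length(cand)) {
      if (phase == 1L) {
        p1 <- sum(r[basis > n])
        if (p1 > 1e-7) { status <- "infeasible"; break }
        ## enter phase 2
        uA[(n + 1L):N] <- 0            # pin artificials at zero
        cc <- c(ifelse(comp, -objW, objW), rep(0, m))
        phase <- 2L
        bland <- FALSE; stall <- 0L; lastz <- Inf
        next
      }
      status <- "optimal"; break
    }

    j <- if (bland) cand[1L] else cand[which.min(d[cand])]
    a <- Tb[, j]

    ## ratio test
    ubasis <- uA[basis]
    pos <- which(a > .LP_PIV_TOL)
    neg <- which(a < -.LP_PIV_TOL & is.finite(ubasis))
    t1 <- if (length(pos)) min(r[pos] / a[pos]) else Inf
    t2 <- if (length(neg)) min((ubasis[neg] - r[neg]) / (-a[neg])) else Inf
    t3 <- uA[j]
    tt <- max(min(t1, t2, t3), 0)
    if (!is.finite(tt)) {
      status <- if (phase == 2L) "unbounded" else "error"
      break
    }

    if (t3 <= min(t1, t2)) {
      ## bound flip: complement entering variable, no basis change
      r <- r - a * t3
      Tb[, j] <- -a
      comp[j] <- !comp[j]
      cc[j] <- -cc[j]
      stall <- stall + 1L
      if (!bland && stall > 2L * (m + n)) bland <- TRUE
      next
    }

    ## leaving row among rows attaining the min ratio
    tol <- .LP_FEAS_TOL * (1 + abs(tt))
    rows1 <- pos[r[pos] / a[pos] <= tt + tol]
    rows2 <- neg[(ubasis[neg] - r[neg]) / (-a[neg]) <= tt + tol]
    allRows <- c(rows1, rows2)
    i <- if (bland) allRows[which.min(basis[allRows])]
         else allRows[which.max(abs(a[allRows]))]
    leavesAtUpper <- (i %in% rows2) && !(i %in% rows1)
    k <- basis[i]

    ## pivot on (i, j)
    piv <- Tb[i, j]
    Tb[i, ] <- Tb[i, ] / piv
    r[i] <- r[i] / piv
    fac <- Tb[, j]
    fac[i] <- 0
    nz <- which(fac != 0)
    if (length(nz)) {
      Tb[nz, ] <- Tb[nz, ] - outer(fac[nz], Tb[i, ])
      r[nz] <- r[nz] - fac[nz] * r[i]
    }
    basis[i] <- j

    if (leavesAtUpper && k <= n) {
      ## departing variable rests at its upper bound: complement it
      ak <- Tb[, k]
      r <- r - ak * uA[k]
      Tb[, k] <- -ak
      comp[k] <- !comp[k]
      cc[k] <- -cc[k]
    }

    r[abs(r) < 1e-12] <- 0
    z <- sum(cc[basis] * r)
    if (z < lastz - 1e-12) { lastz <- z; stall <- 0L }
    else stall <- stall + 1L
    if (!bland && stall > 2L * (m + n)) bland <- TRUE
  }

  if (status != "optimal")
    return(list(status = status, x = rep(NA_real_, n), objval = NA_real_))

  ## recover x in original coordinates
  y <- numeric(n)
  isStruct <- basis <= n
  y[basis[isStruct]] <- r[isStruct]
  y[comp] <- u[comp] - y[comp]
  x <- y + lb
  x <- .lpPolish(A, rhs, lb, ub, x, basis[isStruct], comp)
  list(status = "optimal", x = x, objval = sum(obj * x))
}

# Re-solve the square basic system in original coordinates to remove
# accumulated tableau round-off.  Falls back to the tableau solution if
# the basis matrix is numerically singular or the polished point drifts
# out of bounds.
#' @noRd
.lpPolish <- function(A, rhs, lb, ub, x, sb, comp) {
  n <- ncol(A)
  nb <- setdiff(seq_len(n), sb)
  xN <- numeric(n)
  xN[nb] <- ifelse(comp[nb], ub[nb], lb[nb])
  if (!length(sb)) return(xN)
  rhs2 <- rhs - as.vector(A[, nb, drop = FALSE] %*% xN[nb])
  B <- A[, sb, drop = FALSE]
  sol <- tryCatch(qr.solve(B, rhs2), error = function(e) NULL)
  if (is.null(sol)) return(x)
  xP <- xN
  xP[sb] <- sol
  okB <- all(xP >= lb - 1e-7) && all(xP <= ub + 1e-7)
  okA <- max(abs(as.vector(A %*% xP) - rhs)) <= 1e-7
  if (okB && okA) pmin(pmax(xP, lb), ub) else x
}
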