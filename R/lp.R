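# Thin R-side interface to the compiled bounded-variable simplex. All flux
# optimizations in the package are phrased as
#   max/min  c'x   s.t.  A x = b,  lb <= x <= ub
# with additional linear rows (objective-fraction constraints, parsimony
# budgets) appended together with slack/surplus columns, so a single
# equality-form solver suffices.

# Magnitude used to represent "unbounded" slack variables; model bounds are
# +/-1000 so this never binds.
.LP_BIG <- 1e7

.solveLP <- function(obj, A, b, lb, ub, maximize = TRUE) {
  lb <- pmax(lb, -.LP_BIG)
  ub <- pmin(ub, .LP_BIG)
  res <- .simplex_lp(as.numeric(obj), as.matrix(A), as.numeric(b),
                     as.numeric(lb), as.numeric(ub), maximize)
  if (res$status %in% c("iteration_limit", "numerical_failure"))
    stop("LP solver failed (", res$status, ")")
  res
}

# Dense LP data for a model: list(A, b, lb, ub, c, n) with one column per
# reaction in model order.
.modelLP <- function(model) {
  A <- as.matrix(model@stoichiometry)
  n <- nrow(model@reactions)
  cvec <- numeric(n)
  if (length(model@objective))
    cvec[match(names(model@objective), model@reactions$id)] <- model@objective
  list(A = A, b = numeric(nrow(A)), lb = model@reactions$lower_bound,
       ub = model@reactions$upper_bound, c = cvec, n = n)
}

# Append the row  c'v - s = 0,  s in [fraction*opt, BIG]  which enforces
# c'v >= fraction * opt via the surplus variable s. Returns updated lp with
# one extra column (the surplus) appended last.
.addFractionRow <- function(lp, fraction, opt) {
  m <- nrow(lp$A)
  A <- rbind(cbind(lp$A, 0), c(lp$c, -1))
  list(A = A, b = c(lp$b, 0),
       lb = c(lp$lb, fraction * opt), ub = c(lp$ub, .LP_BIG),
       c = c(lp$c, 0), n = lp$n)
}

# Flux-splitting for taxicab objectives: v = vplus - vminus with
# vplus in [max(lb,0), max(ub,0)], vminus in [max(-ub,0), max(-lb,0)], so
# sum(vplus + vminus) equals sum |v| at any minimum. `extraCols` columns
# (slack variables added by .addFractionRow etc.) are kept unsplit.
.splitLP <- function(lp, extraCols = 0L) {
  n <- lp$n
  Av <- lp$A[, seq_len(n), drop = FALSE]
  Ax <- lp$A[, n + seq_len(extraCols), drop = FALSE]
  A2 <- cbind(Av, -Av, Ax)
  list(A = A2, b = lp$b,
       lb = c(pmax(lp$lb[seq_len(n)], 0), pmax(-lp$ub[seq_len(n)], 0),
              lp$lb[n + seq_len(extraCols)]),
       ub = c(pmax(lp$ub[seq_len(n)], 0), pmax(-lp$lb[seq_len(n)], 0),
              lp$ub[n + seq_len(extraCols)]),
       n = n, extraCols = extraCols)
}

# Recover v from a split-system solution.
.unsplit <- function(x, n) x[seq_len(n)] - x[n + seq_len(n)]

.fluxResult <- function(model, status, x = NULL, objval = NA_real_,
                        method = "fba") {
  v <- stats::setNames(rep(NA_real_, nrow(model@reactions)),
                       model@reactions$id)
  if (!is.null(x)) v[] <- x[seq_len(nrow(model@reactions))]
  methods::new("FluxResult", objectiveValue = as.numeric(objval), fluxes = v,
               status = status, method = method)
}
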