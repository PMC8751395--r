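#' Flux balance analysis
#'
#' Maximizes the model objective \eqn{c'v} subject to the steady-state
#' constraint \eqn{S v = 0} and the flux bounds. Infeasibility and
#' unboundedness are reported through the result status, not as errors.
#'
#' @param model a \linkS4class{MetabolicModel} with a non-empty objective.
#' @return a \linkS4class{FluxResult}.
#' @examples
#' toy <- makeToyModel()
#' fba(toy$model)
#' @export
fba <- function(model) {
  if (!length(model@objective))
    stop("model has no objective; set a non-empty objective vector")
  lp <- .modelLP(model)
  res <- .solveLP(lp$c, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(.fluxResult(model, res$status, method = "fba"))
  .fluxResult(model, "optimal", res$x, res$objval, method = "fba")
}

#' Parsimonious FBA (taxicab-norm minimization)
#'
#' Fixes the objective to at least \code{objectiveFraction} of the FBA
#' optimum, then minimizes the total absolute flux \eqn{\sum_i |v_i|} via
#' the standard non-negative flux splitting \eqn{v = v^+ - v^-}. Minimizing
#' the taxicab norm removes thermodynamically infeasible loops from the
#' reported flux distribution.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objectiveFraction fraction of the FBA optimum the solution must
#'   attain, in (0, 1] (default 1).
#' @return a \linkS4class{FluxResult} attaining the constrained objective.
#' @export
pfba <- function(model, objectiveFraction = 1) {
  stopifnot(objectiveFraction > 0, objectiveFraction <= 1)
  base <- fba(model)
  if (base@status != "optimal")
    return(.fluxResult(model, base@status, method = "pfba"))
  lp <- .addFractionRow(.modelLP(model), objectiveFraction,
                        base@objectiveValue)
  sp <- .splitLP(lp, extraCols = 1L)
  cost <- c(rep(1, 2 * sp$n), numeric(sp$extraCols))
  res <- .solveLP(cost, sp$A, sp$b, sp$lb, sp$ub, maximize = FALSE)
  if (res$status != "optimal")
    return(.fluxResult(model, res$status, method = "pfba"))
  v <- .unsplit(res$x, sp$n)
  lp0 <- .modelLP(model)
  .fluxResult(model, "optimal", v, sum(lp0$c * v), method = "pfba")
}

#' Flux variability analysis
#'
#' For every reaction, computes the minimum and maximum attainable flux
#' subject to \eqn{S v = 0}, the bounds and \eqn{c'v \ge} fraction of the
#' FBA optimum. With \code{loopless = TRUE} each extreme solution is
#' post-processed by a cycle-removal LP (boundary and objective-support
#' fluxes held fixed, internal fluxes sign-restricted toward zero and their
#' total magnitude minimized), so that fluxes sustained only by internal
#' thermodynamically infeasible cycles collapse to zero.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param objectiveFraction fraction of the optimum in (0, 1].
#' @param loopless remove internal-cycle flux from the reported ranges.
#' @param reactionIds reactions to analyse (default all).
#' @return data.frame with columns reaction_id, minimum, maximum,
#'   objective_fraction; attribute \code{"method"} records whether
#'   cycle removal was applied.
#' @export
fva <- function(model, objectiveFraction = 1, loopless = FALSE,
                reactionIds = NULL) {
  stopifnot(objectiveFraction > 0, objectiveFraction <= 1)
  base <- fba(model)
  if (base@status != "optimal")
    stop("FVA requires a feasible bounded model (FBA status: ", base@status,
         "); binding constraints: steady state + bounds + objective")
  lp <- .addFractionRow(.modelLP(model), objectiveFraction,
                        base@objectiveValue)
  if (is.null(reactionIds)) reactionIds <- model@reactions$id
  idx <- match(reactionIds, model@reactions$id)
  if (anyNA(idx))
    stop("unknown reaction ids: ",
         paste(reactionIds[is.na(idx)], collapse = ", "))
  nv <- ncol(lp$A)
  mins <- maxs <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(nv)
    obj[idx[k]] <- 1
    for (dir in c(FALSE, TRUE)) {
      res <- .solveLP(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = dir)
      if (res$status != "optimal")
        stop("FVA subproblem not optimal for ", reactionIds[k],
             " (", res$status, ")")
      val <- if (loopless) {
        v <- .cycleFreeFlux(model, res$x[seq_len(lp$n)])
        v[idx[k]]
      } else res$objval
      if (dir) maxs[k] <- val else mins[k] <- val
    }
  }
  # cycle removal can tighten the two endpoints past each other only by
  # numerical noise; keep the interval ordered
  swap <- mins > maxs
  if (any(swap)) {
    tmp <- mins[swap]; mins[swap] <- maxs[swap]; maxs[swap] <- tmp
  }
  out <- data.frame(reaction_id = reactionIds, minimum = mins, maximum = maxs,
                    objective_fraction = objectiveFraction,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- if (loopless) "fva+cycle-removal" else "fva"
  out
}

# Cycle-removal LP (CycleFreeFlux scheme): given a feasible flux vector v*,
# fix boundary (exchange/sink/demand) and objective-support fluxes at their
# v* values, restrict every internal flux to the closed interval between 0
# and its v* value, and minimize total internal |v|. The result carries the
# same boundary exchange pattern but no internal cycles.
.cycleFreeFlux <- function(model, v) {
  kinds <- model@reactions$kind
  fixed <- kinds %in% c("exchange", "sink", "demand", "objective")
  n <- length(v)
  lb <- ub <- numeric(n)
  lb[fixed] <- ub[fixed] <- v[fixed]
  lb[!fixed] <- pmin(v[!fixed], 0)
  ub[!fixed] <- pmax(v[!fixed], 0)
  cost <- ifelse(fixed, 0, sign(v))  # |v_i| = sign(v*_i) * v_i on these boxes
  A <- as.matrix(model@stoichiometry)
  res <- .solveLP(cost, A, numeric(nrow(A)), lb, ub, maximize = FALSE)
  if (res$status != "optimal") return(v)  # degenerate; keep original
  res$x
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the flux distribution of a perturbed model closest (Euclidean
#' distance) to a wild-type reference: minimizes
#' \eqn{\sum_i (v_i - v^{wt}_i)^2} subject to \eqn{S v = 0}, the bounds and
#' \eqn{v_i = 0} for the disabled reactions. Solved as a quadratic program;
#' a taxicab variant (\code{method = "linear"}) is available for
#' completeness.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param wildTypeFlux a \linkS4class{FluxResult} for the unperturbed model
#'   (an optimal pFBA solution is a good reference).
#' @param disabledReactions character vector of reaction ids forced to zero.
#' @param method "quadratic" (canonical MOMA) or "linear".
#' @return a \linkS4class{FluxResult}; on an infeasible knockout the status
#'   is "infeasible" and the objective value is reported as 0.
#' @export
moma <- function(model, wildTypeFlux, disabledReactions = character(),
                 method = c("quadratic", "linear")) {
  method <- match.arg(method)
  stopifnot(is(wildTypeFlux, "FluxResult"))
  if (wildTypeFlux@status != "optimal")
    stop("wildTypeFlux must be an optimal solution of the unperturbed model")
  w <- wildTypeFlux@fluxes[model@reactions$id]
  n <- length(w)
  lp <- .modelLP(model)
  didx <- match(disabledReactions, model@reactions$id)
  if (anyNA(didx))
    stop("unknown reaction ids: ",
         paste(disabledReactions[is.na(didx)], collapse = ", "))
  lb <- lp$lb; ub <- lp$ub
  lb[didx] <- ub[didx] <- 0
  if (method == "linear") {
    sp <- .splitLP(list(A = lp$A, b = lp$b, lb = lb - w, ub = ub - w,
                        c = lp$c, n = n))
    sp$b <- as.numeric(-lp$A %*% w)
    res <- .solveLP(rep(1, 2 * n), sp$A, sp$b, sp$lb, sp$ub, maximize = FALSE)
    if (res$status != "optimal") {
      out <- .fluxResult(model, "infeasible", method = "moma-linear")
      out@objectiveValue <- 0
      return(out)
    }
    v <- .unsplit(res$x, n) + w
    return(.fluxResult(model, "optimal", v, sum(lp$c * v),
                       method = "moma-linear"))
  }
  # Equality rows: steady state plus the knockouts, reduced to a linearly
  # independent subset (quadprog rejects rank-deficient constraint sets).
  E <- lp$A
  if (length(didx)) {
    ko <- matrix(0, length(didx), n)
    ko[cbind(seq_along(didx), didx)] <- 1
    E <- rbind(E, ko)
  }
  qrE <- qr(t(E))
  E <- E[qrE$pivot[seq_len(qrE$rank)], , drop = FALSE]
  meq <- nrow(E)
  Amat <- cbind(t(E), diag(n), -diag(n))
  bvec <- c(numeric(meq), lb, -ub)
  sol <- tryCatch(
    quadprog::solve.QP(Dmat = diag(n), dvec = as.numeric(w), Amat = Amat,
                       bvec = bvec, meq = meq),
    error = function(e) NULL)
  if (is.null(sol)) {
    out <- .fluxResult(model, "infeasible", method = "moma")
    out@objectiveValue <- 0
    return(out)
  }
  v <- sol$solution
  .fluxResult(model, "optimal", v, sum(lp$c * v), method = "moma")
}

#' Single-gene deletion analysis
#'
#' For each gene, disables every reaction whose GPR rule evaluates to FALSE
#' under the deletion, recomputes growth by FBA or MOMA, and labels the gene
#' essential when mutant growth falls below \code{threshold} times the
#' wild-type growth rate (default 50\%, the usual threshold for comparison
#' with pooled insertion-sequencing screens where slow growers are depleted).
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param geneIds genes to delete (default all model genes).
#' @param method "fba" or "moma". MOMA measures the objective flux of the
#'   mutant distribution closest to a parsimonious wild-type reference.
#' @param threshold essentiality threshold on the growth ratio (default 0.5).
#' @return data.frame with columns gene_id, growth, wild_type, essential,
#'   method.
#' @export
singleGeneDeletion <- function(model, geneIds = NULL,
                               method = c("fba", "moma"), threshold = 0.5) {
  method <- match.arg(method)
  if (is.null(geneIds)) geneIds <- model@genes
  unknown <- setdiff(geneIds, model@genes)
  if (length(unknown))
    stop("unknown gene ids: ", paste(unknown, collapse = ", "))
  wt <- fba(model)
  if (wt@status != "optimal")
    stop("wild-type FBA is not feasible (status: ", wt@status, ")")
  wtGrowth <- wt@objectiveValue
  ref <- if (method == "moma") pfba(model, 1) else wt
  geneSets <- .reactionGeneSets(model)
  growth <- numeric(length(geneIds))
  for (k in seq_along(geneIds)) {
    g <- geneIds[k]
    touches <- vapply(geneSets, function(s) g %in% s, logical(1))
    disabled <- model@reactions$id[touches &
      !vapply(model@reactions$gpr[touches], evaluateGpr, logical(1),
              deletedGenes = g)]
    if (!length(disabled)) {
      growth[k] <- wtGrowth
      next
    }
    if (method == "fba") {
      mut <- fba(setReactionBounds(model, disabled, lower = 0, upper = 0))
      growth[k] <- if (mut@status == "optimal") mut@objectiveValue else 0
    } else {
      mut <- moma(model, ref, disabled)
      growth[k] <- if (mut@status == "optimal") mut@objectiveValue else 0
    }
  }
  data.frame(gene_id = geneIds, growth = growth, wild_type = wtGrowth,
             essential = growth < threshold * wtGrowth, method = method,
             stringsAsFactors = FALSE)
}

# Run fn with a private RNG stream seeded by `seed`; the caller's RNG state
# is untouched.
.withSeed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Sample steady-state flux distributions
#'
#' Draws feasible flux vectors from the polytope \eqn{\{v : S v = 0,
#' lb \le v \le ub\}} by hit-and-run: random directions in the null space of
#' S (restricted to honour fixed reactions), uniform steps within the
#' feasible chord, fixed burn-in and thinning. With \code{weights}, each
#' emitted sample is mixed toward an anchor point that maximizes the
#' weighted flux (each reaction oriented along the direction its
#' taxicab-minimal solution uses), biasing flux toward highly weighted
#' (highly expressed) reactions; the bias is a monotone contract, not a
#' distributional guarantee. Identical seeds give identical samples.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param n number of samples (>= 1).
#' @param seed integer seed (required; the sampler uses a private RNG
#'   stream).
#' @param weights optional named vector, reaction id -> weight in [0, 1].
#' @param burnin,thin hit-and-run burn-in steps and thinning interval.
#' @param mix weight of the anchor point in the emitted convex combination
#'   when \code{weights} are given (default 0.5).
#' @return a \linkS4class{FluxSampleSet}.
#' @export
sampleFluxes <- function(model, n, seed, weights = NULL, burnin = 100,
                         thin = 5, mix = 0.5) {
  stopifnot(n >= 1)
  lp <- .modelLP(model)
  # Start from the taxicab-minimal feasible point (deterministic, feasible).
  sp <- .splitLP(lp)
  res <- .solveLP(rep(1, 2 * lp$n), sp$A, sp$b, sp$lb, sp$ub,
                  maximize = FALSE)
  if (res$status != "optimal")
    stop("model is infeasible; cannot sample (status: ", res$status, ")")
  x0 <- .unsplit(res$x, lp$n)

  anchor <- NULL
  if (!is.null(weights)) {
    wvec <- numeric(lp$n)
    widx <- match(names(weights), model@reactions$id)
    if (anyNA(widx))
      stop("weights name unknown reactions: ",
           paste(names(weights)[is.na(widx)], collapse = ", "))
    wvec[widx] <- pmin(pmax(weights, 0), 1)
    # Anchor: maximize weighted flux magnitude, each reaction oriented along
    # the direction the parsimonious solution uses (sign of x0; +1 for
    # unused reactions). High-weight reactions are pulled toward large
    # |flux|, low-weight reactions contribute almost nothing.
    s <- ifelse(abs(x0) > 1e-9, sign(x0), 1)
    resA <- .solveLP(wvec * s, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
    if (resA$status == "optimal") anchor <- resA$x
  }

  # Null-space basis honouring fixed reactions (lb == ub).
  fixed <- which(lp$ub - lp$lb < 1e-12)
  Saug <- lp$A
  if (length(fixed)) {
    F <- matrix(0, length(fixed), lp$n)
    F[cbind(seq_along(fixed), fixed)] <- 1
    Saug <- rbind(Saug, F)
  }
  qrS <- qr(t(Saug))
  r <- qrS$rank
  N <- if (r < lp$n) qr.Q(qrS, complete = TRUE)[, (r + 1):lp$n, drop = FALSE]
       else matrix(0, lp$n, 0)

  out <- matrix(NA_real_, n, lp$n,
                dimnames = list(NULL, model@reactions$id))
  .withSeed(seed, function() {
    x <- x0
    emit <- 0L
    step <- 0L
    while (emit < n) {
      step <- step + 1L
      if (ncol(N) > 0) {
        d <- as.numeric(N %*% stats::rnorm(ncol(N)))
        nd <- sqrt(sum(d^2))
        if (nd > 1e-12) {
          d <- d / nd
          live <- abs(d) > 1e-12
          lo <- (lp$lb[live] - x[live]) / d[live]
          hi <- (lp$ub[live] - x[live]) / d[live]
          amin <- max(pmin(lo, hi))
          amax <- min(pmax(lo, hi))
          amin <- min(amin, 0)
          amax <- max(amax, 0)
          x <- x + stats::runif(1, amin, amax) * d
        }
      }
      if (step > burnin && step %% thin == 0L) {
        emit <- emit + 1L
        out[emit, ] <<- if (is.null(anchor)) x else mix * anchor +
          (1 - mix) * x
      }
      if (ncol(N) == 0 && step > burnin) {
        # singleton polytope: every sample is the forced point
        while (emit < n) {
          emit <- emit + 1L
          out[emit, ] <<- x
        }
      }
    }
  })
  methods::new("FluxSampleSet", samples = out, seed = as.integer(seed),
               sampler = if (is.null(weights)) "hit-and-run"
                         else sprintf("hit-and-run+anchor(mix=%g)", mix))
}
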