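# Independent oracles used to check the LP layer: exhaustive vertex
# enumeration of {S v = 0, lb <= v <= ub} for small n, and scipy.linprog
# (HiGHS) through the system python for larger fixtures. Both are fully
# independent of the package's own simplex.

# all vertices of the flux polytope (n small; bounds finite)
enumerate_vertices <- function(S, lb, ub, tol = 1e-9) {
  S <- as.matrix(S)
  n <- ncol(S)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  Sq <- rbind(S, matrix(0, nrow = max(0, n - nrow(S)), ncol = n))
  sv <- svd(Sq)
  smax <- if (length(sv$d) > 0) max(sv$d) else 0
  r <- sum(sv$d > 1e-10 * max(smax, 1))
  verts <- list()
  if (r == n) {
    v <- rep(0, n)
    if (all(v >= lb - tol & v <= ub + tol)) verts[[1]] <- v
  } else {
    Ns <- sv$v[, (r + 1):n, drop = FALSE]
    d <- ncol(Ns)
    combos <- utils::combn(n, d)
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), d)))
    for (ci in seq_len(ncol(combos))) {
      J <- combos[, ci]
      M <- Ns[J, , drop = FALSE]
      if (abs(det(M)) < 1e-10) next
      for (si in seq_len(nrow(signs))) {
        bnd <- ifelse(signs[si, ] == 0, lb[J], ub[J])
        v <- as.vector(Ns %*% solve(M, bnd))
        if (all(v >= lb - 1e-7 & v <= ub + 1e-7) &&
            max(abs(S %*% v)) <= 1e-7)
          verts[[length(verts) + 1L]] <- pmin(pmax(v, lb), ub)
      }
    }
  }
  if (length(verts) == 0) return(NULL)
  do.call(rbind, verts)
}

# brute-force optimum by vertex enumeration
vertex_optimum <- function(S, lb, ub, cvec, maximize = TRUE) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(list(status = "infeasible", objective = NA_real_))
  obj <- as.vector(V %*% cvec)
  z <- if (maximize) max(obj) else min(obj)
  list(status = "optimal", objective = z, vertices = V, objectives = obj)
}

# brute-force two-stage lexicographic optimum over vertices
vertex_lexicographic <- function(S, lb, ub, c1, c2, tol = 1e-6) {
  V <- enumerate_vertices(S, lb, ub)
  if (is.null(V)) return(list(status = "infeasible"))
  z1 <- max(as.vector(V %*% c1))
  keep <- as.vector(V %*% c1) >= z1 - tol * max(1, abs(z1))
  z2 <- max(as.vector(V[keep, , drop = FALSE] %*% c2))
  list(status = "optimal", stage1 = z1, stage2 = z2)
}

# batch LP oracle via scipy.optimize.linprog (HiGHS); problems is a list of
# lists with elements A (matrix), b, c, lb, ub, maximize
scipy_lp_batch <- function(problems) {
  stopifnot(length(problems) > 0)
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(problems, function(p) list(
    A = as.matrix(p$A), b = p$b, c = p$c,
    lb = ifelse(is.finite(p$lb), p$lb, -1e30),
    ub = ifelse(is.finite(p$ub), p$ub, 1e30),
    maximize = isTRUE(p$maximize)))
  jsonlite::write_json(payload, infile, digits = NA, auto_unbox = FALSE)
  script <- paste(
    "import json, sys, numpy as np",
    "from scipy.optimize import linprog",
    sprintf("probs = json.load(open(%s))", deparse(infile)),
    "out = []",
    "for p in probs:",
    "    m = len(p['b']); c = np.array(p['c'], float)",
    "    A = np.array(p['A'], float).reshape(m, -1) if m else None",
    "    sgn = -1.0 if p['maximize'][0] else 1.0",
    "    bounds = [(None if l <= -1e29 else l, None if u >= 1e29 else u)",
    "              for l, u in zip(np.ravel(p['lb']), np.ravel(p['ub']))]",
    "    res = linprog(sgn * c, A_eq=A, b_eq=(p['b'] if m else None),",
    "                  bounds=bounds, method='highs')",
    "    st = {0: 'optimal', 2: 'infeasible', 3: 'unbounded'}.get(res.status, 'failed')",
    "    out.append({'status': st,",
    "                'objective': (sgn * res.fun if res.status == 0 else None)})",
    sprintf("json.dump(out, open(%s, 'w'))", deparse(outfile)),
    sep = "\n")
  status <- system2("python", c("-"), input = script, stdout = TRUE,
                    stderr = TRUE)
  if (!file.exists(outfile))
    stop("scipy oracle failed: ", paste(status, collapse = "\n"))
  jsonlite::fromJSON(outfile, simplifyDataFrame = FALSE)
}

# structural reachability: metabolites producible from open exchanges;
# used as a prefilter in the blocked-reaction oracle
producible_closure <- function(model) {
  prod_sets <- lapply(model$reactions, function(r) {
    s <- r$stoichiometry
    if (r$kind == "exchange") return(names(s))        # open boundary
    out <- names(s)[s > 0]
    if (r$reversible) out <- names(s)
    out
  })
  need_sets <- lapply(model$reactions, function(r) {
    s <- r$stoichiometry
    if (r$kind == "exchange") return(character(0))
    names(s)[s < 0]
  })
  producible <- unique(unlist(prod_sets[vapply(model$reactions,
                                               function(r) r$kind == "exchange",
                                               logical(1))]))
  repeat {
    grew <- FALSE
    for (k in seq_along(model$reactions)) {
      if (all(need_sets[[k]] %in% producible)) {
        new <- setdiff(prod_sets[[k]], producible)
        if (length(new) > 0) { producible <- c(producible, new); grew <- TRUE }
      }
    }
    if (!grew) break
  }
  producible
}

# independent blocked-reaction oracle: reachability prefilter + scipy FVA
oracle_blocked <- function(model) {
  open <- model
  for (id in reaction_ids(open)) {
    if (open$reactions[[id]]$kind == "exchange") {
      open$reactions[[id]]$lb <- -1000
      open$reactions[[id]]$ub <- 1000
    }
  }
  S <- as.matrix(build_stoichiometric_matrix(open))
  lb <- vapply(open$reactions, function(r) r$lb, numeric(1))
  ub <- vapply(open$reactions, function(r) r$ub, numeric(1))
  rxns <- reaction_ids(open)
  probs <- list()
  for (k in seq_along(rxns)) {
    cvec <- as.numeric(seq_along(rxns) == k)
    probs[[length(probs) + 1L]] <- list(A = S, b = rep(0, nrow(S)), c = cvec,
                                        lb = lb, ub = ub, maximize = TRUE)
    probs[[length(probs) + 1L]] <- list(A = S, b = rep(0, nrow(S)), c = cvec,
                                        lb = lb, ub = ub, maximize = FALSE)
  }
  res <- scipy_lp_batch(probs)
  blocked <- character(0)
  for (k in seq_along(rxns)) {
    hi <- res[[2 * k - 1]]; lo <- res[[2 * k]]
    if (abs(hi$objective) <= 1e-9 && abs(lo$objective) <= 1e-9)
      blocked <- c(blocked, rxns[k])
  }
  blocked
}
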