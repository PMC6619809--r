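# --- exact 0-1 solver -------------------------------------------------------
#
# The formulations built by build_hostvirus_ip()/build_regulatory_ip() have a
# strong propagation structure: once the path variables are fixed, the linkage
# constraints force every edge and node variable. Depth-first implicit
# enumeration with constraint propagation and an optimistic objective bound is
# therefore exact and fast at the problem sizes this package targets.

EPS_FEAS <- 1e-7

compile_ip <- function(inst, constraints) {
  vnames <- inst$vars$name
  vidx <- structure(seq_along(vnames), names = vnames)
  cons <- map(constraints, function(cn) {
    miss <- setdiff(names(cn$coef), vnames)
    if (length(miss) > 0) {
      abort(sprintf("constraint '%s' references unknown variable '%s'", cn$name, miss[1]))
    }
    list(
      name = cn$name, idx = unname(vidx[names(cn$coef)]),
      coef = unname(cn$coef), sense = cn$sense, rhs = cn$rhs
    )
  })
  var_cons <- vector("list", length(vnames))
  for (ci in seq_along(cons)) {
    for (j in cons[[ci]]$idx) var_cons[[j]] <- c(var_cons[[j]], ci)
  }
  list(vnames = vnames, vidx = vidx, cons = cons, var_cons = var_cons)
}

# fixpoint propagation; returns list(ok, val) with additional forced fixings
bb_propagate <- function(cp, val, queue) {
  cons <- cp$cons
  while (length(queue) > 0) {
    ci <- queue[[1]]
    queue <- queue[-1]
    cn <- cons[[ci]]
    v <- val[cn$idx]
    free <- is.na(v)
    base <- if (all(free)) 0 else sum(cn$coef[!free] * v[!free])
    cf <- cn$coef[free]
    min_act <- base + sum(pmin(cf, 0))
    max_act <- base + sum(pmax(cf, 0))
    force <- integer(0)
    force_val <- integer(0)
    if (cn$sense %in% c("<=", "==")) {
      if (min_act > cn$rhs + EPS_FEAS) return(list(ok = FALSE))
      if (any(free)) {
        fi <- cn$idx[free]
        up <- min_act + abs(cf) # activity if the var takes its max-activity value
        must_flip <- up > cn$rhs + EPS_FEAS
        force <- c(force, fi[must_flip])
        force_val <- c(force_val, ifelse(cf[must_flip] > 0, 0L, 1L))
      }
    }
    if (cn$sense %in% c(">=", "==")) {
      if (max_act < cn$rhs - EPS_FEAS) return(list(ok = FALSE))
      if (any(free)) {
        fi <- cn$idx[free]
        dn <- max_act - abs(cf)
        must_keep <- dn < cn$rhs - EPS_FEAS
        force <- c(force, fi[must_keep])
        force_val <- c(force_val, ifelse(cf[must_keep] > 0, 1L, 0L))
      }
    }
    if (length(force) > 0) {
      clash <- !is.na(val[force]) & val[force] != force_val
      if (any(clash)) return(list(ok = FALSE))
      newly <- is.na(val[force])
      val[force] <- force_val
      for (j in force[newly]) queue <- c(queue, cp$var_cons[[j]])
      if (any(newly)) queue <- c(queue, ci) # re-check with tightened activity
    }
  }
  list(ok = TRUE, val = val)
}

# maximize obj over binary vars subject to cp$cons; returns NULL if infeasible
bb_maximize <- function(cp, obj, node_limit, prefer_one) {
  nv <- length(cp$vnames)
  fam <- attr(obj, "family")
  branch_order <- order(!(fam == "sigma"), -abs(obj))
  st <- new.env(parent = emptyenv())
  st$best <- -Inf
  st$assign <- NULL
  st$nodes <- 0L

  search <- function(val) {
    st$nodes <- st$nodes + 1L
    if (st$nodes > node_limit) abort("solver node limit exceeded", class = "subnetip_node_limit")
    free <- is.na(val)
    bound <- sum(obj[!free] * val[!free]) + sum(pmax(obj[free], 0))
    if (bound <= st$best + 1e-9) {
      return(invisible(NULL))
    }
    if (!any(free)) {
      st$best <- bound
      st$assign <- val
      return(invisible(NULL))
    }
    j <- branch_order[which(is.na(val[branch_order]))[1]]
    first <- if (obj[j] >= 0 || prefer_one[j]) c(1L, 0L) else c(0L, 1L)
    for (b in first) {
      v2 <- val
      v2[j] <- b
      pr <- bb_propagate(cp, v2, cp$var_cons[[j]])
      if (pr$ok) search(pr$val)
    }
    invisible(NULL)
  }

  val0 <- rep(NA_integer_, nv)
  pr <- bb_propagate(cp, val0, seq_along(cp$cons))
  if (pr$ok) search(pr$val)
  if (is.null(st$assign)) {
    return(NULL)
  }
  list(value = st$best, assign = st$assign, nodes = st$nodes)
}

#' Solve an integer program by sequential (lexicographic) optimization
#'
#' Optimizes the instance's objectives in their stated order. After each
#' stage, the achieved value is locked in as a constraint (within a relative
#' tolerance for fractional-coefficient objectives, exactly for integral
#' ones) before the next objective is optimized, so later objectives only
#' break ties among optima of earlier ones. Each stage is solved exactly by
#' depth-first implicit enumeration with constraint propagation and an
#' optimistic bound.
#'
#' @param inst A `subnetip_ip` instance.
#' @param tolerance Relative slack used when locking in a fractional-valued
#'   objective stage (default `1e-6`); integral objectives are locked exactly.
#' @param node_limit Maximum search nodes per stage before erroring.
#' @return A `subnetip_solution`: named binary `$assignment`, named
#'   `$objective_values` in stage order (in each objective's own sense),
#'   `$status` (`"optimal"` or `"infeasible"`) and the search effort
#'   `$nodes`.
#' @export
solve_lexicographic <- function(inst, tolerance = 1e-6, node_limit = 5e5) {
  stopifnot(inherits(inst, "subnetip_ip"))
  nv <- nrow(inst$vars)
  fam <- inst$vars$family
  cons <- inst$constraints
  assign <- NULL
  obj_values <- numeric(0)
  total_nodes <- 0L
  prefer_one <- fam == "sigma" # reach feasible covers quickly

  for (i in seq_along(inst$objectives)) {
    ob <- inst$objectives[[i]]
    dense <- rep(0, nv)
    names(dense) <- inst$vars$name
    dense[names(ob$coef)] <- ob$coef
    sgn <- if (ob$sense == "min") -1 else 1
    obj <- sgn * dense
    attr(obj, "family") <- fam

    cp <- compile_ip(inst, cons)
    res <- tryCatch(
      bb_maximize(cp, obj, node_limit, prefer_one),
      subnetip_node_limit = function(e) {
        abort(sprintf(
          "solver node limit (%g) exceeded at stage %d (%s)", node_limit, i, ob$name
        ))
      }
    )
    if (is.null(res)) {
      if (i > 1) abort(sprintf("internal error: stage %d infeasible after locking stage %d", i, i - 1))
      return(structure(
        list(
          assignment = NULL, objective_values = numeric(0), status = "infeasible",
          nodes = total_nodes, vars = inst$vars, params = inst$params
        ),
        class = "subnetip_solution"
      ))
    }
    v_true <- sgn * res$value
    obj_values <- c(obj_values, structure(v_true, names = ob$name))
    assign <- res$assign
    total_nodes <- total_nodes + res$nodes

    integral <- all(abs(ob$coef - round(ob$coef)) < 1e-9)
    slack <- if (integral) 1e-9 else tolerance * abs(v_true)
    cons[[length(cons) + 1]] <- constraint(
      paste0("stage_lock[", ob$name, "]"), ob$coef,
      if (ob$sense == "max") ">=" else "<=",
      if (ob$sense == "max") v_true - slack else v_true + slack
    )
  }

  structure(
    list(
      assignment = structure(as.integer(assign), names = inst$vars$name),
      objective_values = obj_values, status = "optimal",
      nodes = total_nodes, vars = inst$vars, params = inst$params
    ),
    class = "subnetip_solution"
  )
}

#' @export
print.subnetip_solution <- function(x, ...) {
  cat(sprintf("<subnetip_solution> status: %s\n", x$status))
  if (x$status == "optimal") {
    ov <- paste(sprintf("%s = %g", names(x$objective_values), x$objective_values),
      collapse = ", "
    )
    cat(" ", ov, "\n")
    cat(sprintf(
      "  %d paths, %d edges, %d nodes relevant (%d search nodes)\n",
      sum(x$assignment[x$vars$family == "sigma"]),
      sum(x$assignment[x$vars$family == "x"]),
      sum(x$assignment[x$vars$family == "y"]), x$nodes
    ))
  }
  invisible(x)
}

#' @export
tidy.subnetip_solution <- function(x, ...) {
  if (x$status != "optimal") {
    return(tibble(
      variable = character(), family = character(),
      ref = character(), value = integer()
    ))
  }
  tibble(
    variable = x$vars$name, family = x$vars$family, ref = x$vars$ref,
    value = unname(x$assignment[x$vars$name])
  )
}

#' @export
glance.subnetip_solution <- function(x, ...) {
  out <- tibble(status = x$status, nodes = x$nodes)
  for (nm in names(x$objective_values)) out[[nm]] <- unname(x$objective_values[nm])
  out
}

#' Verify a solution against an instance by direct arithmetic
#'
#' An independent feasibility checker: evaluates every constraint of the
#' instance on the given assignment, without reusing any solver machinery. A
#' solution is feasible iff the returned report has zero rows.
#'
#' @param inst A `subnetip_ip`.
#' @param sol A `subnetip_solution`, or a named 0/1 vector covering all
#'   instance variables.
#' @param tol Numeric slack for constraint satisfaction.
#' @return A tibble of violated constraints
#'   `(constraint, sense, rhs, activity, violation)`.
#' @export
check_solution <- function(inst, sol, tol = 1e-6) {
  stopifnot(inherits(inst, "subnetip_ip"))
  assign <- if (inherits(sol, "subnetip_solution")) sol$assignment else sol
  if (is.null(assign)) abort("solution carries no assignment")
  miss <- setdiff(inst$vars$name, names(assign))
  if (length(miss) > 0) abort(sprintf("assignment missing variable '%s'", miss[1]))

  rows <- map(inst$constraints, function(cn) {
    act <- sum(cn$coef * assign[names(cn$coef)])
    viol <- switch(cn$sense,
      "<=" = max(0, act - cn$rhs),
      ">=" = max(0, cn$rhs - act),
      "==" = abs(act - cn$rhs)
    )
    tibble(
      constraint = cn$name, sense = cn$sense, rhs = cn$rhs,
      activity = act, violation = viol
    )
  })
  filter(bind_rows(rows), .data$violation > tol)
}

#' Extract the inferred subnetwork from a feasible solution
#'
#' Collects the relevant (value-1) paths, edges and nodes of a solution into
#' the inferred subnetwork.
#'
#' @param net A `subnetip_network` (for node annotation).
#' @param ps The `subnetip_paths` the instance was built from.
#' @param sol A feasible `subnetip_solution`.
#' @return A `subnetip_subnetwork` list: `$nodes` (tibble with roles),
#'   `$edges` (tibble of relevant edges), `$paths` (a `subnetip_paths`
#'   restricted to relevant paths).
#' @export
extract_subnetwork <- function(net, ps, sol) {
  stopifnot(inherits(sol, "subnetip_solution"))
  if (sol$status != "optimal") abort("cannot extract a subnetwork from an infeasible solution")
  a <- sol$assignment
  v <- sol$vars
  rel_nodes <- v$ref[v$family == "y" & a[v$name] == 1L]
  rel_edges <- v$ref[v$family == "x" & a[v$name] == 1L]
  rel_paths <- as.integer(v$ref[v$family == "sigma" & a[v$name] == 1L])

  iedges <- instance_edges(ps)
  structure(
    list(
      nodes = filter(net$nodes, .data$id %in% rel_nodes),
      edges = filter(iedges, .data$key %in% rel_edges),
      paths = index_paths(path_list(ps)[rel_paths])
    ),
    class = "subnetip_subnetwork"
  )
}

#' @export
print.subnetip_subnetwork <- function(x, ...) {
  cat(sprintf(
    "<subnetip_subnetwork> %d nodes, %d edges, %d paths\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$paths$paths)
  ))
  invisible(x)
}

#' Write a solution's variable assignment to TSV
#' @param sol A `subnetip_solution`.
#' @param path Destination file.
#' @return Invisibly, `sol`.
#' @export
write_solution <- function(sol, path) {
  readr::write_tsv(tidy(sol), path)
  invisible(sol)
}
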