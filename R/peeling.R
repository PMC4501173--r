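# Elston-Stewart peeling over the combined major-genotype x polygene state
# space. A pedigree is decomposed into nuclear-family units; units are
# peeled from the periphery inwards, each unit collapsing onto the single
# member ("connector") that links it to the rest of the pedigree, until
# only the designated root individual carries a state vector. Pedigrees
# with marriage or inbreeding loops never become peelable and are rejected.

# Build the peeling plan for one family. `root_id` is the individual whose
# state vector survives to the end (defaults to the proband); it is never
# eliminated, so its final vector is proportional to its posterior.
plan_family <- function(p, root_id = NULL) {
  n <- nrow(p)
  ids <- p$id
  fa <- match(p$father_id, ids)
  mo <- match(p$mother_id, ids)
  if (any(is.na(fa) != is.na(mo))) {
    stop("individuals must have both parents in the family or neither", call. = FALSE)
  }
  founder <- is.na(fa)
  if (is.null(root_id)) root_id <- ids[which(p$proband)[1]]
  root <- match(root_id, ids)
  if (is.na(root)) stop("root individual not in family", call. = FALSE)

  # nuclear-family units
  key <- ifelse(founder, NA, paste(fa, mo))
  units <- list()
  for (k in unique(stats::na.omit(key))) {
    ch <- which(!is.na(key) & key == k)
    units[[length(units) + 1L]] <- list(fa = fa[ch[1]], mo = mo[ch[1]], children = ch)
  }
  nunit <- length(units)
  membership <- vector("list", n)
  for (u in seq_len(nunit)) {
    for (m in c(units[[u]]$fa, units[[u]]$mo, units[[u]]$children)) {
      membership[[m]] <- c(membership[[m]], u)
    }
  }
  count <- lengths(membership)
  single_unit <- count == 1L        # candidates for analytic marginalisation
  count[root] <- count[root] + 1L   # phantom membership: never eliminate root

  steps <- list()
  peeled <- rep(FALSE, nunit)
  repeat {
    if (all(peeled)) break
    progressed <- FALSE
    for (u in which(!peeled)) {
      mem <- c(units[[u]]$fa, units[[u]]$mo, units[[u]]$children)
      busy <- mem[count[mem] > 1L]
      if (length(busy) > 1L) next
      conn <- if (length(busy) == 1L) busy else mem[length(mem)]
      steps[[length(steps) + 1L]] <- list(
        fa = units[[u]]$fa, mo = units[[u]]$mo,
        children = units[[u]]$children, conn = conn,
        conn_role = if (conn %in% c(units[[u]]$fa, units[[u]]$mo)) "parent" else "child"
      )
      count[mem] <- count[mem] - 1L
      peeled[u] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) {
      stop("pedigree contains a marriage or inbreeding loop: unsupported structure",
           call. = FALSE)
    }
  }
  eliminated <- rep(FALSE, n)
  for (s in steps) {
    mem <- c(s$fa, s$mo, s$children)
    eliminated[setdiff(mem, s$conn)] <- TRUE
  }
  list(n = n, ids = ids, founder = founder, root = root, steps = steps,
       single_unit = single_unit, leftover = which(!eliminated))
}

# Child-elimination matrix K[s_m, s_f] = sum_{s_c} T(s_c | s_m, s_f) V(s_c)
peel_child_full <- function(ctx, v) {
  G <- ctx$G; R <- ctx$R
  dim(v) <- c(G, R)
  M1 <- ctx$TPmat %*% t(v)                 # (rm,rf) x gc
  K <- ctx$TMmat %*% t(M1)                 # (gm,gf) x (rm,rf)
  K <- K[ctx$perm_K]
  dim(K) <- c(G * R, G * R)                # [s_m, s_f]
  K
}

# As above with the father integrated out analytically (founder, no data):
# k[s_m] = sum_{s_c} T'(s_c | s_m) V(s_c)
peel_child_avg <- function(ctx, v) {
  as.vector(crossprod(ctx$TMavg, matrix(v, ctx$G, ctx$R)) %*% ctx$TPavg)
}

# Transmission applied to a joint parent factor W[s_m, s_f]:
# msg[s_c] = sum_{s_m, s_f} T(s_c | s_m, s_f) W[s_m, s_f]
transmit_from_couple <- function(ctx, W) {
  G <- ctx$G; R <- ctx$R
  Wp <- W[ctx$perm_W]
  dim(Wp) <- c(R * R, G * G)               # rows (rm,rf), cols (gm,gf)
  A <- crossprod(ctx$TPmat, Wp)            # rc x (gm,gf)
  as.vector(t(A %*% ctx$TMmat))            # g fastest
}

# msg[s_c] = sum_{s_m} T'(s_c | s_m) U[s_m]
transmit_from_single <- function(ctx, u) {
  as.vector(ctx$TMavg %*% matrix(u, ctx$G, ctx$R) %*% t(ctx$TPavg))
}

is_const_col <- function(x) {
  r <- range(x)
  r[2] - r[1] <= 1e-14 * max(r[2], 1)
}

# Execute a peeling plan. PEN is the raw penetrance matrix (states x
# members, founder priors NOT included). Returns list(loglik, post) where
# `post` is the root's unnormalised state vector with the rest of the
# pedigree absorbed (NULL when the likelihood is zero).
peel_exec <- function(ctx, plan, PEN) {
  V <- PEN
  for (i in which(plan$founder)) V[, i] <- V[, i] * ctx$prior
  logscale <- 0
  const_col <- plan$founder & plan$single_unit &
    .colSums(abs(PEN - rep(PEN[1, ], each = nrow(PEN))), nrow(PEN), ncol(PEN)) == 0
  const_col[plan$root] <- FALSE

  for (s in plan$steps) {
    fa <- s$fa; mo <- s$mo
    triv <- function(i) const_col[i]
    if (s$conn_role == "parent") {
      # normalise so the connector sits in the `mo` slot (transmission is
      # symmetric in the parents)
      if (s$conn == fa) { tmp <- fa; fa <- mo; mo <- tmp }
      kids <- s$children
      # a data-less founder parent can be integrated out analytically only
      # when there is a single child: siblings remain correlated through
      # the shared parent's genotype
      if (length(kids) == 1L && triv(fa)) {
        msg <- rep(PEN[1, fa], ctx$nstates)
        for (c in kids) msg <- msg * peel_child_avg(ctx, V[, c])
      } else {
        KP <- matrix(1, ctx$nstates, ctx$nstates)
        for (c in kids) KP <- KP * peel_child_full(ctx, V[, c])
        msg <- as.vector(KP %*% V[, fa])
      }
      V[, mo] <- V[, mo] * msg
      conn <- mo
    } else {
      x <- s$conn
      others <- setdiff(s$children, x)
      fa_t <- triv(fa); mo_t <- triv(mo)
      if (mo_t && !fa_t) { tmp <- fa; fa <- mo; mo <- tmp; fa_t <- TRUE }
      if (length(others) == 0L && fa_t) {
        u <- V[, mo] * PEN[1, fa]   # father's constant penetrance enters once
        for (c in others) u <- u * peel_child_avg(ctx, V[, c])
        msg <- transmit_from_single(ctx, u)
      } else {
        W <- V[, mo] %o% V[, fa]
        for (c in others) W <- W * peel_child_full(ctx, V[, c])
        msg <- transmit_from_couple(ctx, W)
      }
      V[, x] <- V[, x] * msg
      conn <- x
    }
    m <- max(V[, conn])
    if (!is.finite(m) || m <= 0) return(list(loglik = -Inf, post = NULL))
    V[, conn] <- V[, conn] / m
    logscale <- logscale + log(m)
  }

  loglik <- logscale
  post <- NULL
  for (i in plan$leftover) {
    tot <- sum(V[, i])
    if (tot <= 0) return(list(loglik = -Inf, post = NULL))
    if (i == plan$root) post <- V[, i]
    loglik <- loglik + log(tot)
  }
  list(loglik = loglik, post = post)
}

family_loglik <- function(ctx, p, root_id = NULL, override_values = NULL,
                          plan = NULL, PEN = NULL) {
  if (is.null(plan)) plan <- plan_family(p, root_id)
  if (is.null(PEN)) PEN <- pen_matrix(ctx, p, override_values)
  peel_exec(ctx, plan, PEN)
}
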