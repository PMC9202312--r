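# Compiled evaluation of Hamilton-function tables.
#
# table_value() / table_grad() in einsum.R are the transparent reference
# implementations.  For propagation, the same computation is compiled once
# per (method, orbital dimensions) into flat lists of primitive operations
# (precomputed gather indices, reshapes and matrix products), removing the
# per-call interpretive overhead.  Tests cross-check the two paths.

.plan_cache <- new.env(parent = emptyenv())

.letter_len <- function(letter, nocc, norb) {
  .idx_len(.idx_class(letter), nocc, norb)
}

# ---- factor prep compilation ----------------------------------------------
# A prep turns a stored tensor into a dense block over its distinct kept
# letters (internal repeats collapsed to diagonals, fully-internal letters
# traced out) via one gather plus an optional trailing-axis sum.
.compile_prep <- function(name, letters, traced, nocc, norb) {
  cls <- .idx_class(letters)
  native <- .NATIVE_BLOCKS[[name]]
  if (!is.null(native) && !identical(cls, native)) {
    stop("factor ", name, " letters do not match its native block")
  }
  nat_dims <- if (is.null(native)) rep(norb, length(letters)) else
    vapply(native, .idx_len, integer(1), nocc = nocc, norb = norb)
  dl <- unique(letters)
  kept <- setdiff(dl, traced)
  ord <- c(kept, intersect(dl, traced))
  lens <- vapply(ord, .letter_len, integer(1), nocc = nocc, norb = norb)
  grid <- do.call(expand.grid, lapply(lens, seq_len))
  names(grid) <- ord
  strides <- cumprod(c(1, nat_dims))[seq_along(nat_dims)]
  gi <- rep(1, nrow(grid))
  for (ax in seq_along(letters)) {
    off <- if (is.null(native) && cls[ax] == "v") nocc else 0L
    gi <- gi + (grid[[letters[ax]]] - 1L + off) * strides[ax]
  }
  kept_lens <- lens[seq_len(length(kept))]
  ntrace <- if (length(ord) > length(kept))
    prod(lens[(length(kept) + 1L):length(ord)]) else 1L
  list(name = name, gi = as.integer(gi), kept = kept,
       kept_dims = as.integer(kept_lens), ntrace = as.integer(ntrace))
}

.run_prep <- function(prep, tensors) {
  x <- tensors[[prep$name]][prep$gi]
  if (prep$ntrace > 1L) {
    nk <- prod(prep$kept_dims)
    dim(x) <- c(max(nk, 1L), prep$ntrace)
    x <- x %*% rep(1 + 0i, prep$ntrace)
  }
  if (length(prep$kept) == 0L) return(as.complex(x)[1])
  dim(x) <- prep$kept_dims
  x
}

# ---- fold compilation ------------------------------------------------------
# Compile the left-to-right fold of prepared factors (letters/dims known)
# down to `out_letters`.  Returns list(ops, out_letters_actual).
.compile_fold <- function(facs, out_letters, nocc, norb) {
  # facs: list of list(id, letters); dims implied by letters
  ops <- list()
  dims_of <- function(letters) {
    vapply(letters, .letter_len, integer(1), nocc = nocc, norb = norb)
  }
  sum_away <- function(cur, drop) {
    if (length(drop) == 0L) return(cur)
    keep <- setdiff(cur$letters, drop)
    perm <- c(match(keep, cur$letters), match(drop, cur$letters))
    nd <- prod(dims_of(drop))
    ops[[length(ops) + 1L]] <<- list(op = "sumax", perm = perm,
                                     ident_a = identical(perm, seq_along(perm)),
                                     nk = prod(dims_of(keep)),
                                     nd = nd, ones = rep(1 + 0i, nd),
                                     out_dims = dims_of(keep))
    cur$letters <- keep
    cur
  }
  all_letters <- lapply(facs, `[[`, "letters")
  cur <- list(letters = facs[[1]]$letters)
  ops[[1]] <- list(op = "load", id = facs[[1]]$id)
  later <- unique(unlist(all_letters[-1]))
  cur <- sum_away(cur, setdiff(cur$letters, c(later, out_letters)))
  if (length(facs) > 1L) {
    for (k in 2:length(facs)) {
      nxt <- facs[[k]]
      later <- if (k < length(facs))
        unique(unlist(all_letters[(k + 1):length(all_letters)])) else character()
      cs <- setdiff(intersect(cur$letters, nxt$letters), c(later, out_letters))
      afree <- setdiff(cur$letters, cs)
      bfree <- setdiff(nxt$letters, cs)
      pa <- c(match(afree, cur$letters), match(cs, cur$letters))
      pb <- c(match(cs, nxt$letters), match(bfree, nxt$letters))
      ops[[length(ops) + 1L]] <- list(
        op = "pair", id = nxt$id, pa = pa, pb = pb,
        ident_a = identical(pa, seq_along(pa)),
        ident_b = identical(pb, seq_along(pb)),
        na = prod(dims_of(afree)), nc = prod(dims_of(cs)),
        nb = prod(dims_of(bfree)),
        out_dims = c(dims_of(afree), dims_of(bfree)))
      cur$letters <- c(afree, bfree)
      cur <- sum_away(cur, setdiff(cur$letters, c(later, out_letters)))
    }
  }
  list(ops = ops, letters = cur$letters)
}

.run_fold <- function(ops, prepped) {
  cur <- NULL
  for (o in ops) {
    if (o$op == "load") {
      cur <- prepped[[o$id]]
    } else if (o$op == "sumax") {
      if (is.null(dim(cur))) next  # already scalar
      if (!o$ident_a) cur <- aperm(cur, o$perm)
      dim(cur) <- c(o$nk, o$nd)
      cur <- cur %*% o$ones
      if (length(o$out_dims) > 0L) dim(cur) <- o$out_dims else cur <- cur[1]
    } else { # pair
      B <- prepped[[o$id]]
      if (is.null(dim(cur)) || length(dim(cur)) == 0L) {
        cur <- as.complex(cur)[1] * B
        next
      }
      if (!o$ident_a) cur <- aperm(cur, o$pa)
      dim(cur) <- c(o$na, o$nc)
      if (!o$ident_b) B <- aperm(B, o$pb)
      dim(B) <- c(o$nc, o$nb)
      cur <- cur %*% B
      if (length(o$out_dims) > 0L) dim(cur) <- o$out_dims else cur <- cur[1]
    }
  }
  cur
}

# ---- whole-table compilation ----------------------------------------------

compile_hamiltonian <- function(method, nocc, norb) {
  key <- paste(method, nocc, norb, sep = "|")
  if (!is.null(.plan_cache[[key]])) return(.plan_cache[[key]])
  terms <- hamilton_terms(method)
  grads <- intersect(c("l1", "l2", "t2", "h", "v", "fb"),
                     unique(unlist(lapply(terms, function(tm) {
                       vapply(tm$factors, `[[`, "", "name")
                     }))))
  preps <- list(); prep_ids <- character()
  get_prep <- function(name, letters, traced) {
    key2 <- paste(name, paste(letters, collapse = ""),
                  paste(sort(traced), collapse = ""), sep = ":")
    hit <- match(key2, prep_ids)
    if (!is.na(hit)) return(hit)
    preps[[length(preps) + 1L]] <<- .compile_prep(name, letters, traced,
                                                  nocc, norb)
    prep_ids[length(preps)] <<- key2
    length(preps)
  }
  term_plans <- vector("list", length(terms))
  for (ti in seq_along(terms)) {
    tm <- terms[[ti]]
    lets <- lapply(tm$factors, `[[`, "letters")
    facs <- vector("list", length(tm$factors))
    for (k in seq_along(tm$factors)) {
      fl <- lets[[k]]
      elsewhere <- unique(unlist(lets[-k]))
      traced <- setdiff(unique(fl[duplicated(fl)]), elsewhere)
      id <- get_prep(tm$factors[[k]]$name, fl, traced)
      facs[[k]] <- list(id = id, letters = setdiff(unique(fl), traced))
    }
    has_lambda <- any(vapply(tm$factors, function(f)
      f$name %in% c("l1", "l2"), logical(1)))
    fold <- .compile_fold(facs, character(), nocc, norb)
    # gradient occurrences
    gocc <- list()
    for (w in grads) {
      hits <- which(vapply(tm$factors, function(f) f$name == w, logical(1)))
      for (hx in hits) {
        fl <- lets[[hx]]
        fcls <- .idx_class(fl)
        dl <- unique(fl)
        other_letters <- unique(unlist(lets[-hx]))
        keep <- intersect(dl, other_letters)
        if (length(tm$factors) > 1L) {
          cfold <- .compile_fold(facs[-hx], keep, nocc, norb)
          keep_order <- cfold$letters
        } else {
          cfold <- NULL
          keep_order <- character()
        }
        # grid over distinct letters (first fastest)
        lens <- vapply(dl, .letter_len, integer(1), nocc = nocc, norb = norb)
        grid <- do.call(expand.grid, lapply(lens, seq_len))
        names(grid) <- dl
        native <- .NATIVE_BLOCKS[[w]]
        nat_dims <- if (is.null(native)) rep(norb, length(fl)) else
          vapply(native, .idx_len, integer(1), nocc = nocc, norb = norb)
        strides <- cumprod(c(1, nat_dims))[seq_along(nat_dims)]
        lin <- rep(1, nrow(grid))
        for (ax in seq_along(fl)) {
          off <- if (is.null(native) && fcls[ax] == "v") nocc else 0L
          lin <- lin + (grid[[fl[ax]]] - 1L + off) * strides[ax]
        }
        gidx <- NULL
        if (length(keep_order) > 0L) {
          clens <- vapply(keep_order, .letter_len, integer(1),
                          nocc = nocc, norb = norb)
          cstr <- cumprod(c(1, clens))[seq_along(clens)]
          gidx <- rep(1, nrow(grid))
          for (ax in seq_along(keep_order)) {
            gidx <- gidx + (grid[[keep_order[ax]]] - 1L) * cstr[ax]
          }
          gidx <- as.integer(gidx)
        }
        gocc[[length(gocc) + 1L]] <- list(
          wrt = w, fold = if (is.null(cfold)) NULL else cfold$ops,
          lin = as.integer(lin), gidx = gidx)
      }
    }
    term_plans[[ti]] <- list(coef = tm$coef, fold = fold$ops,
                             has_lambda = has_lambda, gocc = gocc)
  }
  grad_dims <- lapply(grads, function(w) {
    native <- .NATIVE_BLOCKS[[w]]
    if (is.null(native)) {
      if (w %in% c("h", "fb")) c(norb, norb) else rep(norb, 4L)
    } else {
      vapply(native, .idx_len, integer(1), nocc = nocc, norb = norb)
    }
  })
  names(grad_dims) <- grads
  plan <- list(preps = preps, terms = term_plans, grads = grads,
               grad_dims = grad_dims)
  .plan_cache[[key]] <- plan
  plan
}

# Evaluate a compiled plan: returns value, energy-only value and requested
# gradients.
eval_compiled <- function(plan, tensors, grads = character()) {
  prepped <- lapply(plan$preps, .run_prep, tensors = tensors)
  total <- 0 + 0i
  etotal <- 0 + 0i
  g <- lapply(plan$grad_dims[grads], function(d) array(0 + 0i, dim = d))
  for (tp in plan$terms) {
    v <- .run_fold(tp$fold, prepped)
    total <- total + tp$coef * v
    if (!tp$has_lambda) etotal <- etotal + tp$coef * v
    for (go in tp$gocc) {
      if (!(go$wrt %in% grads)) next
      if (is.null(go$fold)) {
        vals <- tp$coef
      } else {
        cof <- .run_fold(go$fold, prepped)
        if (is.null(go$gidx)) {
          vals <- tp$coef * as.complex(cof)[1]
        } else {
          vals <- tp$coef * cof[go$gidx]
        }
      }
      gw <- g[[go$wrt]]
      gw[go$lin] <- gw[go$lin] + vals
      g[[go$wrt]] <- gw
    }
  }
  list(value = total, energy_value = etotal, grad = g)
}
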