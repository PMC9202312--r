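# Tensor-contraction engine used by all equation-of-motion code.
#
# Index-letter convention (fixed across the package, documented once here and
# enforced by the integral validator):
#   occupied  spin orbitals: i j k l m n   (range 1..n_occ)
#   virtual   spin orbitals: a b c d e f   (range n_occ+1..L)
#   general   spin orbitals: p q r s       (range 1..L)
# Tensors are stored with upper (creation) indices as leading axes, so the
# two-body element v_rs^pq lives at v[p, q, r, s].

.OCC_LETTERS  <- c("i", "j", "k", "l", "m", "n")
.VIRT_LETTERS <- c("a", "b", "c", "d", "e", "f")
.GEN_LETTERS  <- c("p", "q", "r", "s")

.idx_class <- function(letters) {
  cls <- character(length(letters))
  cls[letters %in% .OCC_LETTERS] <- "o"
  cls[letters %in% .VIRT_LETTERS] <- "v"
  cls[letters %in% .GEN_LETTERS] <- "g"
  if (any(cls == "")) {
    stop("unknown index letter(s): ",
         paste(letters[cls == ""], collapse = ", "))
  }
  cls
}

.idx_range <- function(class, nocc, norb) {
  switch(class,
         o = seq_len(nocc),
         v = seq.int(nocc + 1L, norb),
         g = seq_len(norb),
         stop("bad index class"))
}

.idx_len <- function(class, nocc, norb) {
  as.integer(switch(class, o = nocc, v = norb - nocc, g = norb))
}

#' @noRd
.as_array <- function(x) {
  if (is.null(dim(x))) array(x, dim = length(x)) else x
}

# Sum an array over the axes listed in `drop_axes`.
.sum_axes <- function(arr, drop_axes) {
  if (length(drop_axes) == 0L) return(arr)
  d <- dim(arr)
  keep <- setdiff(seq_along(d), drop_axes)
  if (length(keep) == 0L) return(sum(arr))
  res <- apply(arr, keep, sum)
  if (is.null(dim(res))) res <- array(res, dim = d[keep])
  res
}

# Extract the joint diagonal of two axes (pos1 < pos2), keeping a single axis
# (placed last) for the shared index.
.diag_axes <- function(arr, pos1, pos2) {
  d <- dim(arr)
  stopifnot(d[pos1] == d[pos2])
  n <- d[pos1]
  rest <- setdiff(seq_along(d), c(pos1, pos2))
  perm <- c(rest, pos1, pos2)
  a <- aperm(arr, perm)
  r <- prod(d[rest])
  dim(a) <- c(r, n * n)
  diag_cols <- (seq_len(n) - 1L) * n + seq_len(n)
  a <- a[, diag_cols, drop = FALSE]
  dim(a) <- c(d[rest], n)
  a
}

# Collapse repeated letters inside a single factor to one axis each; letters in
# `trace_now` (repeated and absent from the rest of the term) are summed out.
.collapse_factor <- function(arr, letters, trace_now) {
  repeat {
    dup <- letters[duplicated(letters)]
    if (length(dup) == 0L) break
    lt <- dup[[1]]
    pos <- which(letters == lt)
    arr <- .diag_axes(arr, pos[1], pos[2])
    letters <- c(letters[-pos], lt)
  }
  drop <- which(letters %in% trace_now)
  if (length(drop) > 0L) {
    arr <- .as_array(.sum_axes(arr, drop))
    letters <- letters[-drop]
  }
  list(arr = .as_array(arr), letters = letters)
}

# Binary tensor contraction: sums over `sum_letters`; free letters keep the
# order (A-free, B-free).
.pair_contract <- function(A, al, B, bl, sum_letters) {
  if (length(al) == 0L) return(list(arr = as.complex(A)[1] * B, letters = bl))
  if (length(bl) == 0L) return(list(arr = A * as.complex(B)[1], letters = al))
  da <- dim(A); db <- dim(B)
  cs <- intersect(intersect(al, bl), sum_letters)
  afree <- setdiff(al, cs)
  bfree <- setdiff(bl, cs)
  pa <- c(match(afree, al), match(cs, al))
  pb <- c(match(cs, bl), match(bfree, bl))
  A <- aperm(A, pa); B <- aperm(B, pb)
  na <- prod(da[match(afree, al)])
  nc <- prod(da[match(cs, al)])
  nb <- prod(db[match(bfree, bl)])
  dim(A) <- c(max(na, 1L), max(nc, 1L))
  dim(B) <- c(max(nc, 1L), max(nb, 1L))
  R <- A %*% B
  out_dims <- c(da[match(afree, al)], db[match(bfree, bl)])
  if (length(out_dims) == 0L) return(list(arr = R[1, 1], letters = character()))
  dim(R) <- out_dims
  list(arr = R, letters = c(afree, bfree))
}

# Fold a list of (array, letters) down to the indices in `out_letters`
# (order respected).  All other letters are summed.
.fold_contract <- function(pieces, out_letters) {
  if (length(pieces) == 0L) stop("empty contraction")
  all_letters <- lapply(pieces, `[[`, "letters")
  cur <- pieces[[1]]
  # sum out letters unique to the first factor and not wanted in the output
  later <- unique(unlist(all_letters[-1]))
  drop <- setdiff(cur$letters, c(later, out_letters))
  if (length(drop)) {
    cur$arr <- .as_array(.sum_axes(cur$arr, match(drop, cur$letters)))
    cur$letters <- setdiff(cur$letters, drop)
  }
  if (length(pieces) > 1L) {
    for (k in 2:length(pieces)) {
      nxt <- pieces[[k]]
      later <- if (k < length(pieces)) unique(unlist(all_letters[(k + 1):length(all_letters)])) else character()
      sum_letters <- setdiff(union(cur$letters, nxt$letters), c(later, out_letters))
      cur <- .pair_contract(cur$arr, cur$letters, nxt$arr, nxt$letters, sum_letters)
      drop <- setdiff(cur$letters, c(later, out_letters))
      if (length(drop)) {
        cur$arr <- .as_array(.sum_axes(cur$arr, match(drop, cur$letters)))
        cur$letters <- setdiff(cur$letters, drop)
      }
    }
  }
  if (length(out_letters) == 0L) {
    return(if (length(cur$letters) == 0L) as.complex(cur$arr)[1] else sum(cur$arr))
  }
  aperm(.as_array(cur$arr), match(out_letters, cur$letters))
}

# ---------------------------------------------------------------------------
# Term tables
#
# A term is list(coef, factors) with factors a list of c(name, index-string).
# The scalar value of a table is sum_terms coef * contraction(factors).
# Named tensors are either stored over the full orbital range (native class
# "g" on every axis: h, v, fb, dipole components) or as blocks with fixed
# classes (t2: "vvoo", l1: "ov", l2: "oovv", t1: "vo").

.NATIVE_BLOCKS <- list(t2 = c("v", "v", "o", "o"),
                       l2 = c("o", "o", "v", "v"),
                       l1 = c("o", "v"),
                       t1 = c("v", "o"))

.term <- function(coef, ...) {
  facs <- list(...)
  list(coef = coef,
       factors = lapply(facs, function(f) {
         list(name = f[[1]], letters = strsplit(f[[2]], "")[[1]])
       }))
}

# Slice the block of a full-range tensor addressed by typed letters.
.slice_full <- function(arr, classes, nocc, norb) {
  idx <- lapply(classes, .idx_range, nocc = nocc, norb = norb)
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# Prepare one factor: slice (full tensors), check classes (block tensors),
# collapse internal repeats.  `elsewhere` = letters appearing in the other
# factors of the same term (internal repeats not in `elsewhere` are traced).
.prep_factor <- function(fac, tensors, nocc, norb, elsewhere) {
  arr <- tensors[[fac$name]]
  if (is.null(arr)) stop("missing tensor: ", fac$name)
  letters <- fac$letters
  cls <- .idx_class(letters)
  native <- .NATIVE_BLOCKS[[fac$name]]
  if (is.null(native)) {
    arr <- .slice_full(arr, cls, nocc, norb)
  } else {
    if (!identical(cls, native)) {
      stop("factor ", fac$name, "[", paste(letters, collapse = ""),
           "] does not match native block ", paste(native, collapse = ""))
    }
  }
  dup <- unique(letters[duplicated(letters)])
  trace_now <- setdiff(dup, elsewhere)
  .collapse_factor(.as_array(arr), letters, trace_now)
}

# Scalar value of a term table.
table_value <- function(terms, tensors, nocc, norb) {
  total <- 0 + 0i
  for (tm in terms) {
    letters_by_fac <- lapply(tm$factors, `[[`, "letters")
    pieces <- vector("list", length(tm$factors))
    for (k in seq_along(tm$factors)) {
      elsewhere <- unique(unlist(letters_by_fac[-k]))
      pieces[[k]] <- .prep_factor(tm$factors[[k]], tensors, nocc, norb, elsewhere)
    }
    total <- total + tm$coef * .fold_contract(pieces, character())
  }
  total
}

# Gradient of the scalar table value with respect to tensor `wrt`, treating
# every stored element as independent.  Returns an array of the native shape
# of `wrt` (full L-range for "g" tensors, block shape otherwise).
table_grad <- function(terms, tensors, wrt, nocc, norb) {
  native <- .NATIVE_BLOCKS[[wrt]]
  proto <- tensors[[wrt]]
  if (is.null(proto)) stop("missing tensor: ", wrt)
  g <- array(0 + 0i, dim = dim(.as_array(proto)))
  for (tm in terms) {
    hits <- which(vapply(tm$factors, function(f) f$name == wrt, logical(1)))
    if (length(hits) == 0L) next
    letters_by_fac <- lapply(tm$factors, `[[`, "letters")
    for (h in hits) {
      fl <- letters_by_fac[[h]]
      fcls <- .idx_class(fl)
      others <- tm$factors[-h]
      other_letters <- unique(unlist(letters_by_fac[-h]))
      distinct <- unique(fl)
      keep <- intersect(distinct, other_letters)
      if (length(others) > 0L) {
        pieces <- vector("list", length(others))
        ol <- lapply(others, `[[`, "letters")
        for (k in seq_along(others)) {
          elsewhere <- unique(c(unlist(ol[-k]), fl))
          pieces[[k]] <- .prep_factor(others[[k]], tensors, nocc, norb, elsewhere)
        }
        cof <- .fold_contract(pieces, keep)
      } else {
        cof <- 1 + 0i
      }
      # index grid over the distinct letters of this factor
      lens <- vapply(.idx_class(distinct), .idx_len, integer(1),
                     nocc = nocc, norb = norb)
      grid <- as.matrix(do.call(expand.grid,
                                lapply(lens, seq_len)))
      colnames(grid) <- distinct
      # cofactor values on the grid (letters in `keep`; others broadcast)
      if (length(keep) > 0L) {
        vals <- .as_array(cof)[grid[, keep, drop = FALSE]]
      } else {
        vals <- rep(cof, nrow(grid))
      }
      # embed into the native array of `wrt`
      d <- dim(g)
      if (is.null(native)) {
        offs <- vapply(fcls, function(cl) {
          if (cl == "v") as.integer(nocc) else 0L
        }, integer(1))
      } else {
        offs <- rep(0L, length(fcls))
      }
      lin <- rep(1, nrow(grid))
      stride <- 1
      for (ax in seq_along(fl)) {
        lin <- lin + (grid[, fl[ax]] - 1L + offs[ax]) * stride
        stride <- stride * d[ax]
      }
      g[lin] <- g[lin] + tm$coef * vals
    }
  }
  g
}
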