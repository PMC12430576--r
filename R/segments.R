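# Internal interval algebra over donor-origin chromosome segments.
# A homolog is a 2-column matrix of half-open bp intervals [start, end),
# sorted and disjoint; an empty matrix means fully recurrent-parent.

seg_empty <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

seg_full <- function(length_bp) {
  matrix(c(1, length_bp + 1), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

# Clip a sorted disjoint segment set to [a, b)
seg_clip <- function(seg, a, b) {
  if (nrow(seg) == 0L || a >= b) return(seg_empty())
  s <- pmax(seg[, 1L], a)
  e <- pmin(seg[, 2L], b)
  keep <- s < e
  if (!any(keep)) return(seg_empty())
  matrix(c(s[keep], e[keep]), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

# Union of two sorted disjoint segment sets (result sorted/disjoint; touching
# intervals merge)
seg_union <- function(a, b) {
  m <- rbind(a, b)
  if (nrow(m) == 0L) return(seg_empty())
  m <- m[order(m[, 1L]), , drop = FALSE]
  s <- m[1L, 1L]; e <- m[1L, 2L]
  out_s <- numeric(0); out_e <- numeric(0)
  if (nrow(m) > 1L) {
    for (i in 2L:nrow(m)) {
      if (m[i, 1L] <= e) {
        e <- max(e, m[i, 2L])
      } else {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        s <- m[i, 1L]; e <- m[i, 2L]
      }
    }
  }
  out_s <- c(out_s, s); out_e <- c(out_e, e)
  matrix(c(out_s, out_e), ncol = 2L, dimnames = list(NULL, c("start", "end")))
}

# Total bp covered
seg_width <- function(seg) {
  if (nrow(seg) == 0L) return(0)
  sum(seg[, 2L] - seg[, 1L])
}

# Membership of 1-based positions: TRUE where pos falls in a segment.
# Relies on half-open boundaries flattened to a sorted vector: a position is
# inside iff findInterval() lands on an odd index.
seg_contains <- function(seg, pos) {
  if (nrow(seg) == 0L) return(rep(FALSE, length(pos)))
  bounds <- as.vector(t(seg))
  findInterval(pos, bounds) %% 2L == 1L
}

# One meiosis: transmit a recombinant gamete from homolog pair (h1, h2) on a
# chromosome of length_bp with the given genetic map length (Morgans).
# Haldane model: crossover count ~ Poisson(map length), positions uniform in bp
# (uniform cM/bp), no interference.  Returns the donor-segment set of the
# transmitted haplotype.
meiosis_gamete <- function(h1, h2, length_bp, map_morgans) {
  n_xo <- stats::rpois(1L, map_morgans)
  cuts <- if (n_xo > 0L) sort(stats::runif(n_xo, min = 1, max = length_bp + 1)) else numeric(0)
  bounds <- c(1, cuts, length_bp + 1)
  phase <- sample.int(2L, 1L)
  out <- seg_empty()
  for (i in seq_len(length(bounds) - 1L)) {
    src <- if ((i + phase) %% 2L == 0L) h1 else h2
    piece <- seg_clip(src, bounds[i], bounds[i + 1L])
    if (nrow(piece) > 0L) out <- seg_union(out, piece)
  }
  out
}
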