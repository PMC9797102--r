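# Standard genetic code and precomputed Nei-Gojobori codon tables.
#
# Codons are indexed 1..64 as 16*A + 4*B + C + 1 with A,B,C in
# {T=0, C=1, A=2, G=3} (the classical codon-table ordering).

.ng_bases <- c("T", "C", "A", "G")

# amino acids in TCAG order, "*" = stop
.ng_aa64 <- c(
  "F", "F", "L", "L", "S", "S", "S", "S", "Y", "Y", "*", "*", "C", "C", "*", "W",
  "L", "L", "L", "L", "P", "P", "P", "P", "H", "H", "Q", "Q", "R", "R", "R", "R",
  "I", "I", "I", "M", "T", "T", "T", "T", "N", "N", "K", "K", "S", "S", "R", "R",
  "V", "V", "V", "V", "A", "A", "A", "A", "D", "D", "E", "E", "G", "G", "G", "G"
)

.ng_codon_strings <- function() {
  g <- expand.grid(c3 = .ng_bases, c2 = .ng_bases, c1 = .ng_bases,
                   stringsAsFactors = FALSE)
  paste0(g$c1, g$c2, g$c3)
}

# codon string -> index 1..64, NA for anything outside {A,C,G,T}^3
.ng_codon_index <- function(codons) {
  m <- match(codons, .ng_codon_strings())
  m
}

.ng_is_stop <- function(idx) .ng_aa64[idx] == "*"

# Digits (0..3 in TCAG order) of codon index i at positions 1..3.
.ng_digits <- function(idx) {
  i0 <- idx - 1L
  cbind(i0 %/% 16L, (i0 %/% 4L) %% 4L, i0 %% 4L)
}

.ng_from_digits <- function(d) d[, 1] * 16L + d[, 2] * 4L + d[, 3] + 1L

# environment caching the per-codon site fractions and the 64 x 64
# pathway-averaged difference tables; built once per session
.ng_cache <- new.env(parent = emptyenv())

.ng_site_table <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache$sites)
  syn <- rep(NA_real_, 64)
  for (i in seq_len(64)) {
    if (.ng_is_stop(i)) next
    d <- .ng_digits(i)[1, ]
    s <- 0
    for (pos in 1:3) {
      for (alt in 0:3) {
        if (alt == d[pos]) next
        d2 <- d
        d2[pos] <- alt
        j <- d2[1] * 16L + d2[2] * 4L + d2[3] + 1L
        # mutation to a stop codon counts as nonsynonymous
        if (!.ng_is_stop(j) && .ng_aa64[j] == .ng_aa64[i]) s <- s + 1 / 3
      }
    }
    syn[i] <- s
  }
  .ng_cache$sites <- cbind(n = 3 - syn, s = syn)
  .ng_cache$sites
}

# All permutations of 1..n (n <= 3 here), one per row.
.ng_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    sub <- .ng_perms(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Pathway-averaged (nonsyn, syn) differences between two non-stop codons,
# plus a flag when every minimal pathway transits a stop codon (in which
# case stop-transit pathways are included rather than dropping the pair).
.ng_diff_tables <- function() {
  if (!is.null(.ng_cache$diff)) return(.ng_cache$diff)
  nd <- matrix(NA_real_, 64, 64)
  sd_ <- matrix(NA_real_, 64, 64)
  stopflag <- matrix(FALSE, 64, 64)
  aa <- .ng_aa64
  for (i in seq_len(64)) {
    if (.ng_is_stop(i)) next
    di <- .ng_digits(i)[1, ]
    for (j in seq_len(64)) {
      if (.ng_is_stop(j)) next
      dj <- .ng_digits(j)[1, ]
      pos <- which(di != dj)
      h <- length(pos)
      if (h == 0) {
        nd[i, j] <- 0; sd_[i, j] <- 0
        next
      }
      perms <- .ng_perms(h)
      path_n <- numeric(0)
      path_s <- numeric(0)
      path_ok <- logical(0)
      for (p in seq_len(nrow(perms))) {
        cur <- di
        nn <- 0; ss <- 0; ok <- TRUE
        for (step in perms[p, seq_len(h)]) {
          nxt <- cur
          nxt[pos[step]] <- dj[pos[step]]
          a1 <- aa[cur[1] * 16L + cur[2] * 4L + cur[3] + 1L]
          a2 <- aa[nxt[1] * 16L + nxt[2] * 4L + nxt[3] + 1L]
          if (a2 == "*") ok <- FALSE
          if (a1 == a2) ss <- ss + 1 else nn <- nn + 1
          cur <- nxt
        }
        path_n <- c(path_n, nn); path_s <- c(path_s, ss); path_ok <- c(path_ok, ok)
      }
      if (any(path_ok)) {
        nd[i, j] <- mean(path_n[path_ok])
        sd_[i, j] <- mean(path_s[path_ok])
      } else {
        nd[i, j] <- mean(path_n)
        sd_[i, j] <- mean(path_s)
        stopflag[i, j] <- TRUE
      }
    }
  }
  .ng_cache$diff <- list(n = nd, s = sd_, stop_transit = stopflag)
  .ng_cache$diff
}
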