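# Independent oracles and small fixture builders used across the suite.

# Recursive coancestry (kinship) by path counting with memoisation; completely
# independent of the tabular-method implementation. a(i,j) = 2 f(i,j).
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  depth <- integer(n)
  repeat {
    nd <- pmax(ifelse(is.na(si), 0L, depth[ifelse(is.na(si), 1L, si)] + 1L),
               ifelse(is.na(di), 0L, depth[ifelse(is.na(di), 1L, di)] + 1L))
    if (all(nd == depth)) break
    depth <- nd
  }
  memo <- new.env(hash = TRUE)
  f <- function(i, j) {
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste(i, j)
    if (!is.null(v <- memo[[key]])) return(v)
    v <- if (i == j) {
      0.5 * (1 + if (!is.na(si[i]) && !is.na(di[i])) f(si[i], di[i]) else 0)
    } else {
      # recurse on the animal further from the founders
      k <- if (depth[j] >= depth[i]) j else i
      o <- if (k == j) i else j
      fs <- if (!is.na(si[k])) f(si[k], o) else 0
      fd <- if (!is.na(di[k])) f(di[k], o) else 0
      0.5 * (fs + fd)
    }
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in i:n) A[i, j] <- A[j, i] <- 2 * f(i, j)
  A
}

# random valid pedigree: animals numbered in birth order, parents drawn from
# strictly earlier animals (or unknown)
random_pedigree <- function(n, p_known = 0.7) {
  animal <- paste0("x", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i >= 3 && runif(1) < p_known) {
      pick <- sample(i - 1L, 2L)
      sire[i] <- animal[pick[1]]; dam[i] <- animal[pick[2]]
    }
  }
  data.frame(animal = animal, sire = sire, dam = dam,
             stringsAsFactors = FALSE)
}

# full-sib mating pedigree: s, d founders; o1, o2 full sibs; x = o1 x o2
fullsib_pedigree <- function() {
  data.frame(animal = c("s", "d", "o1", "o2", "x"),
             sire = c("0", "0", "s", "s", "o1"),
             dam = c("0", "0", "d", "d", "o2"),
             stringsAsFactors = FALSE)
}

# brute-force shortest HPD window (independent of hpd_interval)
hpd_bruteforce <- function(x, prob = 0.95) {
  s <- sort(x); n <- length(s); m <- ceiling(prob * n)
  if (m >= n) return(c(s[1], s[n]))
  best <- c(s[1], s[m]); bw <- s[m] - s[1]
  for (k in 2:(n - m + 1)) {
    w <- s[k + m - 1] - s[k]
    if (w < bw - 1e-15) { bw <- w; best <- c(s[k], s[k + m - 1]) }
  }
  best
}

# small linear-trait simulation bundle used by several inference tests
quick_sim <- function(seed, n_founders = 150, gens = 3, G0 = matrix(4),
                      R0 = matrix(6), traits = list(trait_spec("y")),
                      cg_count = 8) {
  cfg <- sim_config(n_founders = n_founders, n_generations = gens,
                    n_snps = 5, traits = traits, G0 = as.matrix(G0),
                    R0 = as.matrix(R0), cg_count = cg_count, seed = seed)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, cfg$G0, seed = seed + 1)
  phe <- simulate_phenotypes(ped, bv, cfg, seed = seed + 2)
  list(cfg = cfg, ped = ped, bv = bv, phe = phe)
}
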