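# Shared helpers: sum-of-atoms mass oracle, tiny spectrum builders,
# brute-force reference implementations used as independent oracles.

## independent sum-of-atoms oracle (kept separate from the package's
## residue table on purpose: atoms, not residues)
atom_mass <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)
oracle_formula_mass <- function(C = 0, H = 0, N = 0, O = 0, S = 0) {
  sum(atom_mass * c(C, H, N, O, S))
}
## residue formulas: Hex C6H10O5, HexNAc C8H13NO5, dHex C6H10O4,
## Neu5Ac C11H17NO8, Neu5Gc C11H17NO9, HexA C6H8O6, SO3, C2H2O
oracle_residue <- list(
  hex = c(C = 6, H = 10, O = 5), hexnac = c(C = 8, H = 13, N = 1, O = 5),
  dhex = c(C = 6, H = 10, O = 4), neu5ac = c(C = 11, H = 17, N = 1, O = 8),
  neu5gc = c(C = 11, H = 17, N = 1, O = 9), hexa = c(C = 6, H = 8, O = 6),
  sulfate = c(S = 1, O = 3), acetyl = c(C = 2, H = 2, O = 1))
oracle_mass <- function(counts, water = FALSE, reduced = FALSE,
                        protons = 0) {
  f <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  for (nm in names(counts))
    f <- f + counts[[nm]] * c(oracle_residue[[nm]],
                              c(C = 0, H = 0, N = 0, O = 0, S = 0))[names(f)]
  m <- do.call(oracle_formula_mass, as.list(f))
  if (water) m <- m + oracle_formula_mass(H = 2, O = 1)
  if (reduced) m <- m + oracle_formula_mass(H = 2)
  m + protons * 1.00727646688
}

## quick spectrum constructor
make_spec <- function(mz, intensity, id = "s1", precursor_mz = 1000,
                      charge = 2L, rt = 600, sample = "test") {
  spectrum(id = id, precursor_mz = precursor_mz, charge = charge, rt = rt,
           mz = mz, intensity = intensity, sample = sample)
}

## brute-force composition enumeration oracle: nested loops + explicit
## predicate, independent of the package's vectorized path
oracle_enumerate <- function(cons) {
  out <- list()
  for (hx in seq(cons$hex[1], cons$hex[2]))
    for (hn in seq(cons$hexnac[1], cons$hexnac[2]))
      for (dh in seq(cons$dhex[1], cons$dhex[2]))
        for (na in seq(cons$neu5ac[1], cons$neu5ac[2]))
          for (ng in seq(cons$neu5gc[1], cons$neu5gc[2])) {
            non_core <- hn - 2
            if (non_core < 0 || non_core > cons$max_antennae + 1) next
            ant <- min(non_core, cons$max_antennae)
            if (hn == 2) {
              if (hx > 9 || na + ng > 0 || dh > 1) next
            } else {
              hx_max <- 3 + 2 * ant + if (non_core <= 2) 2 else 0
              if (hx < 3 || hx > hx_max) next
              if (na + ng > ant + as.integer(cons$allow_disialyl)) next
            }
            if (dh > ant + 1) next
            m <- oracle_mass(list(hex = hx, hexnac = hn, dhex = dh,
                                  neu5ac = na, neu5gc = ng),
                             water = TRUE, reduced = TRUE, protons = 1)
            if (m < cons$mass_range[1] || m > cons$mass_range[2]) next
            out[[length(out) + 1L]] <-
              format_composition(composition(hex = hx, hexnac = hn,
                                             dhex = dh, neu5ac = na,
                                             neu5gc = ng))
          }
  sort(unique(unlist(out)))
}

## brute-force Ward (ward.D2) agglomeration oracle via Lance-Williams
oracle_ward <- function(mat) {
  n <- nrow(mat)
  d2 <- as.matrix(stats::dist(mat))^2  # squared Euclidean
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  merges <- list()
  cluster_id <- -seq_len(n)            # hclust convention
  next_id <- 0L
  while (length(active) > 1) {
    best <- c(NA, NA); bestval <- Inf
    for (a in seq_along(active)) for (b in seq_len(a - 1)) {
      i <- active[a]; j <- active[b]
      if (d2[i, j] < bestval) { bestval <- d2[i, j]; best <- c(j, i) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(bestval))
    next_id <- next_id + 1L
    merges[[next_id]] <- sort(c(cluster_id[i], cluster_id[j]))
    ## Lance-Williams update for ward.D2 on squared distances
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                  nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2new
    }
    sizes[i] <- ni + nj
    cluster_id[i] <- next_id
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}
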