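# In-code fixtures and independent oracles shared across the suite.

# Quick PrSM tibble in the internal representation.
make_prsms <- function(run_id = "R1", cv = -40L, mass, rt,
                       accession = "P00001", evalue = 1e-8,
                       proteoform = "M.SGRGK.A", qvalue = 0.001,
                       intensity = NA_real_, engine = "toppic") {
  n <- max(length(mass), length(rt))
  mods <- parse_proteoform_mods(rep_len(proteoform, n))
  tibble::tibble(
    engine = engine, run_id = rep_len(run_id, n), cv = rep_len(cv, n),
    scan = as.character(seq_len(n)), rt_min = rep_len(rt, n),
    precursor_mass = rep_len(mass, n), adjusted_mass = NA_real_,
    charge = 8L, evalue = rep_len(evalue, n),
    qvalue = rep_len(qvalue, n), accession = rep_len(accession, n),
    gene = NA_character_, first_residue = 2L, last_residue = 6L,
    proteoform = rep_len(proteoform, n),
    intensity = rep_len(intensity, n), modifications = mods,
    has_unknown_shift = tdpquant:::has_unknown_mass_shift(mods)
  )
}

make_features <- function(run_id = "R1", cv = -40L, mass, rt, abundance = 1) {
  n <- max(length(mass), length(rt))
  tibble::tibble(
    run_id = rep_len(run_id, n), cv = rep_len(cv, n),
    mono_mass = rep_len(mass, n), rt_apex = rep_len(rt, n),
    rt_start = rep_len(rt, n) - 0.5, rt_end = rep_len(rt, n) + 0.5,
    abundance = rep_len(abundance, n), charge_min = 5L, charge_max = 12L
  )
}

# Independent oracle: chained grouping by explicit scan over the sorted
# vector (one gap rule at a time).
oracle_chain_groups <- function(x, breaks_fun) {
  if (length(x) == 0) return(integer(0))
  g <- integer(length(x))
  g[1] <- 1L
  for (i in seq_along(x)[-1]) {
    g[i] <- if (breaks_fun(x[i - 1], x[i])) g[i - 1] + 1L else g[i - 1]
  }
  g
}

# Independent oracle: single-linkage components by breadth-first search
# over the full pairwise adjacency matrix.
oracle_components <- function(n, link_mat) {
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(link_mat[v, ] & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Canonical form of a partition (for comparing partitions irrespective of
# label values): sorted list of sorted member index sets.
partition_canonical <- function(labels) {
  unname(lapply(sort(unique(labels)), function(l) which(labels == l))) |>
    (\(x) x[order(vapply(x, min, integer(1)))])()
}

# Histone H4 mature chain (residues 2-103 of the canonical sequence,
# initiator Met removed); identical in rat and human.
H4_MATURE_CHAIN <- paste0(
  "SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKPAIRRLARRGGVKRISGLIYEETRGVLKV",
  "FLENVIRDAVTYTEHAKRKTVTAMDVVYALKRQGRTLYGFGG")
ACETYL_DA <- 42.010565
DIMETHYL_DA <- 2 * 14.015650
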