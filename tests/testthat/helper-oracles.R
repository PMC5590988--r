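# Shared fixtures and independent oracles, built in code at test time.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Exhaustive walk enumeration: expands the multiset of walk endpoints one
# edge at a time and tabulates endpoints per cost.  Independent of the
# layered counting DP it is used to check (no per-vertex recurrences).
enum_walk_counts <- function(edges, s, cost_hi, max_walks = 2e6) {
  verts <- sort(unique(c(edges$from, edges$to, s)))
  counts <- matrix(0, nrow = length(verts), ncol = cost_hi + 1L,
                   dimnames = list(verts, 0:cost_hi))
  frontier <- s  # multiset of endpoints of all walks of current cost
  counts[s, 1L] <- 1
  for (i in seq_len(cost_hi)) {
    nxt <- unlist(lapply(frontier, function(v) edges$to[edges$from == v]),
                  use.names = FALSE)
    if (length(nxt) == 0) break
    if (length(nxt) > max_walks) stop("oracle walk explosion")
    tab <- table(nxt)
    counts[names(tab), i + 1L] <- as.numeric(tab)
    frontier <- nxt
  }
  counts
}

# Random directed graph on letter-labelled vertices (self-loops allowed).
random_edge_list <- function(n_vertices, p_edge = 0.25) {
  verts <- LETTERS[seq_len(n_vertices)]
  pairs <- expand.grid(from = verts, to = verts, stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < p_edge
  pairs[keep, , drop = FALSE]
}

# Reads tiling a sequence so that every (k+1)-mer is covered.
tiling_reads <- function(seq, read_len, step) {
  n <- nchar(seq)
  starts <- unique(c(seq(1L, max(1L, n - read_len + 1L), by = step),
                     max(1L, n - read_len + 1L)))
  substring(seq, starts, pmin(starts + read_len - 1L, n))
}

# Small planted-insertion world shared by gapfill/genotype tests.
make_planted_world <- function(ref_len = 4000L, ins_len = 300L,
                               p = 2000L, cfg = NULL, seed = 42L) {
  set.seed(seed)
  ref <- make_reference(ref_len)
  ins <- random_dna(ins_len)
  donor <- paste0(substr(ref, 1, p), ins, substr(ref, p + 1, ref_len))
  if (is.null(cfg))
    cfg <- sim_config(reference_length = ref_len, n_insertions = 0L,
                      mean_insert = 400, sd_insert = 40, coverage = 30)
  rd <- simulate_reads(donor, cfg)
  list(ref = ref, ins = ins, donor = donor, p = p, reads = rd$reads,
       read_truth = rd$truth, cfg = cfg)
}
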