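# Shared fixtures, built once per test run and cached.  Everything is
# generated in code from fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small genome with one element of every placement kind
small_genome <- function() {
  fixture("small_genome", function() {
    specs <- list(
      element_spec("A", lineage = "A"),
      element_spec("D", insertion_offset = -11L),
      element_spec("D", insertion_offset = 5L),
      element_spec("D+Myb2", truncate5_nt = 500L),
      element_spec("no-Myb"),
      element_spec("C", site_specific = FALSE))
    build_genome_and_truth(specs, n_rdna_units = 6, seed = 3)
  })
}

# the architecture panel: every label x every first-pair variant where the
# label has a finger to vary, plus plain copies, 50 specs in total
arch_panel_specs <- function() {
  fixture("arch_panel", function() {
    labels <- c("A", "B", "C", "D", "D+Myb2", "4ZnF", "no-Myb")
    variants <- c("CxC", "CxxC", "CxxxC", "CPCC")
    specs <- list()
    for (lab in labels) {
      fingers <- switch(lab, "A" = c(3, 2, 1), "B" = c(2, 1), "C" = c(3, 1),
                        "D" = 1, "D+Myb2" = 1, "4ZnF" = c(4, 3, 2, 1),
                        "no-Myb" = 1)
      for (v in variants) {
        # vary the most N-terminal finger's first-pair spacing; after
        # positional numbering that finger carries the highest assigned
        # number, i.e. the finger count (for label C the generator's ZnF3
        # is assigned number 2 -- positional numbering cannot know which
        # finger was lost, which is why B/C use pair type)
        vf <- as.character(max(fingers))
        specs[[length(specs) + 1L]] <- list(
          spec = element_spec(lab, znf_variants = setNames(v, vf)),
          label = lab, check_number = length(fingers), variant = v)
      }
    }
    # pad with default-variant copies to 50
    i <- 0L
    while (length(specs) < 50L) {
      lab <- labels[(i %% length(labels)) + 1L]
      specs[[length(specs) + 1L]] <- list(spec = element_spec(lab),
                                          label = lab,
                                          check_number = NA_integer_,
                                          variant = "CxxC")
      i <- i + 1L
    }
    specs
  })
}

# independent enumeration oracle for the zinc-finger grammar: brute-force
# loops over every (start, spacing, gap) combination, then the same stated
# selection rule, coded separately from the implementation
oracle_znf <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  raw <- list()
  for (c1 in seq_len(n)) {
    if (ch[c1] != "C") next
    for (s in 1:3) {
      c2 <- c1 + s + 1L
      if (c2 > n || ch[c2] != "C") next
      for (g1 in 8:14) {
        hp <- c2 + g1 + 1L
        if (hp > n || ch[hp] != "H") next
        for (g2 in 3:5) {
          lp <- hp + g2 + 1L
          if (lp > n) next
          if (ch[lp] == "H" || ch[lp] == "C")
            raw[[length(raw) + 1L]] <- c(c1, lp, s,
                                         cpcc = as.integer(
                                           c1 + 3L <= n &&
                                             ch[c1 + 1L] == "P" &&
                                             ch[c1 + 2L] == "C" &&
                                             ch[c1 + 3L] == "C"))
        }
      }
    }
  }
  if (!length(raw)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, raw)
  pref <- !(m[, 4] == 1L & m[, 3] == 2L)
  o <- order(m[, 1], pref, m[, 3], m[, 2])
  m <- m[o, , drop = FALSE]
  sel <- integer(0); last_end <- 0L
  for (i in seq_len(nrow(m))) {
    if (m[i, 1] > last_end) { sel <- c(sel, i); last_end <- m[i, 2] }
  }
  data.frame(start = m[sel, 1] - 1L, end = m[sel, 2])
}

# brute-force local alignment oracle: enumerate all substring pairs and all
# monotone alignment paths between them (exponential; tiny inputs only)
oracle_local_align <- function(a, b, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  gap_cost <- function(k) gap_open + gap_extend * k
  best <- 0
  score_path <- function(i, j, li, lj) {
    # best global score of a[i..i+li-1] vs b[j..j+lj-1], full enumeration
    rec <- function(x, y) {
      if (x == 0 && y == 0) return(0)
      out <- -Inf
      if (x > 0 && y > 0) {
        s <- if (av[i + x - 1L] == bv[j + y - 1L]) match else mismatch
        out <- max(out, rec(x - 1L, y - 1L) + s)
      }
      if (x > 0) for (k in 1:x) out <- max(out, rec(x - k, y) - gap_cost(k))
      if (y > 0) for (k in 1:y) out <- max(out, rec(x, y - k) - gap_cost(k))
      out
    }
    rec(li, lj)
  }
  na <- length(av); nb <- length(bv)
  for (i in seq_len(na)) for (li in seq_len(na - i + 1L))
    for (j in seq_len(nb)) for (lj in seq_len(nb - j + 1L))
      best <- max(best, score_path(i, j, li, lj))
  best
}

# brute-force likelihood by enumerating all internal-node states
oracle_tree_lik <- function(phy, aln, rate) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  S <- ncol(aln)
  pm <- function(t) r2scout:::pmat_poisson(t * rate)
  Ps <- lapply(seq_len(nrow(phy$edge)), function(e) pm(phy$edge.length[e]))
  out <- numeric(S)
  states <- as.matrix(expand.grid(rep(list(1:20), nint)))
  for (s in seq_len(S)) {
    tot <- 0
    tip_state <- aln[phy$tip.label, s]
    for (r in seq_len(nrow(states))) {
      node_state <- c(tip_state, states[r, ])
      pr <- 1 / 20
      for (e in seq_len(nrow(phy$edge))) {
        par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
        if (node_state[child] == 0L) next  # missing tip marginalises out
        pr <- pr * Ps[[e]][node_state[par], node_state[child]]
      }
      tot <- tot + pr
    }
    out[s] <- tot
  }
  out
}

random_aa_string <- function(n, alphabet = r2scout:::.AA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
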