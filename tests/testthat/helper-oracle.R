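# Independent brute-force enumerator used as the completeness oracle for
# synthesize_exhaustive. It performs a plain recursive all-attachments
# search over assembly sequences (no level structure, no intermediate
# deduplication) directly on the fragment annotations, and deduplicates the
# final set by canonical key only. It shares nothing with the synthesizer
# except the canonicalization primitive.

oracle_enumerate <- function(lib, max_level) {
  lib <- ensure_descriptors(lib)
  ids <- sort(names(lib$fragments))
  frag_states <- lapply(ids, function(id) {
    f <- lib$fragments[[id]]
    n <- nrow(f$graph$atoms)
    allowed <- rep(list(character(0)), n)
    conn <- integer(n)
    if (f$kind == "rigid") {
      for (a in names(f$conn)) allowed[[as.integer(a)]] <- f$conn[[a]]
    } else {
      conn <- if (identical(f$mode, "unsaturated")) {
        pmin(f$conn$orig, f$conn$sat)
      } else {
        f$conn$sat
      }
    }
    list(atoms = f$graph$atoms, bonds = f$graph$bonds,
         kind = rep(f$kind, n), allowed = allowed, conn = conn, level = 1L)
  })

  graphs <- list()
  record <- function(st) {
    graphs[[length(graphs) + 1L]] <<- molecule_graph(st$atoms, st$bonds,
                                                     validate = FALSE)
  }

  open_ok <- function(st, i) {
    if (st$atoms$hcount[i] < 1L) return(FALSE)
    if (st$kind[i] == "rigid") length(st$allowed[[i]]) > 0L else
      st$conn[i] >= 1L
  }

  attach_frag <- function(st, a, fs, b) {
    n1 <- nrow(st$atoms)
    atoms <- rbind(st$atoms, fs$atoms)
    rownames(atoms) <- NULL
    fb <- fs$bonds; fb$i <- fb$i + n1; fb$j <- fb$j + n1
    bonds <- rbind(st$bonds, fb, data.frame(i = a, j = b + n1, order = 1L))
    atoms$hcount[a] <- atoms$hcount[a] - 1L
    atoms$hcount[b + n1] <- atoms$hcount[b + n1] - 1L
    out <- list(atoms = atoms, bonds = bonds,
                kind = c(st$kind, fs$kind),
                allowed = c(st$allowed, fs$allowed),
                conn = c(st$conn, fs$conn), level = st$level + 1L)
    if (out$kind[a] == "linker") out$conn[a] <- out$conn[a] - 1L
    if (out$kind[b + n1] == "linker") out$conn[b + n1] <- out$conn[b + n1] - 1L
    out
  }

  recurse <- function(st) {
    record(st)
    if (st$level >= max_level) return()
    for (fs in frag_states) {
      for (a in seq_len(nrow(st$atoms))) {
        if (!open_ok(st, a)) next
        for (b in seq_len(nrow(fs$atoms))) {
          if (!open_ok(fs, b)) next
          ka <- st$kind[a]; kb <- fs$kind[b]
          if (ka == "linker" && kb == "linker") next
          if (ka == "rigid" && !(fs$atoms$sybyl[b] %in% st$allowed[[a]])) next
          if (kb == "rigid" && !(st$atoms$sybyl[a] %in% fs$allowed[[b]])) next
          recurse(attach_frag(st, a, fs, b))
        }
      }
    }
  }

  for (fs in frag_states) recurse(fs)
  sort(unique(canonical_keys(graphs)))
}

# Deterministic generator of small random libraries (<= 4 fragments,
# <= 6 open connections in total) for the oracle-equivalence sweep.
random_small_library <- function(seed) {
  set.seed(seed)
  rigid_pool <- c("c1ccccc1", "c1ccncc1", "c1ccsc1", "c1ccoc1")
  linker_pool <- c("C", "CC", "CCN", "OC=O")
  partner_pool <- c("C.3", "N.3", "C.ar")
  frags <- list()
  n_frag <- sample(2:4, 1L)
  n_rigid <- max(1L, sample.int(n_frag, 1L) - 1L)
  for (k in seq_len(n_frag)) {
    if (k <= n_rigid) {
      g <- smiles_to_molecule(sample(rigid_pool, 1L), sprintf("r%d", k))
      f <- new_fragment("rigid", g)
      ar <- which(g$atoms$sybyl == "C.ar" & g$atoms$hcount >= 1L)
      site <- sample(ar, 1L)
      f$conn[[as.character(site)]] <-
        sort(sample(partner_pool, sample(1:2, 1L)))
      frags[[k]] <- f
    } else {
      g <- smiles_to_molecule(sample(linker_pool, 1L), sprintf("l%d", k))
      f <- new_fragment("linker", g)
      f$conn$orig <- pmin(g$atoms$hcount,
                          sample(0:1, nrow(g$atoms), replace = TRUE))
      if (sum(f$conn$orig) == 0L) f$conn$orig[1] <- 1L
      frags[[k]] <- f
    }
  }
  lib <- consolidate(frags, linker_mode = "unsaturated")
  open <- 0L
  for (f in lib$fragments) {
    open <- open + if (f$kind == "rigid") {
      sum(vapply(names(f$conn), function(a) {
        min(1L, f$graph$atoms$hcount[as.integer(a)])
      }, integer(1)))
    } else {
      max_connections(f)
    }
  }
  if (open > 6L) return(NULL)
  lib
}
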