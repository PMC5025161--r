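# Independent pure-R oracles: deliberately different implementation routes
# from the package's C++ (explicit O(V^2) adjacency instead of on-demand
# hash lookups), used to cross-check graph operations on small inputs.

r_revcomp <- function(s) {
  chartr("ACGT", "TGCA",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""), ""))
}

r_canon <- function(s) pmin(s, unname(r_revcomp(s)))

r_kmers <- function(seqs, k) {
  out <- character(0)
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    out <- c(out, substring(s, 1:(n - k + 1), k:n))
  }
  out
}

# canonical k-mer count table, brute force
r_count_kmers <- function(seqs, k, min_count = 1) {
  tab <- table(r_canon(r_kmers(seqs, k)))
  tab <- tab[tab >= min_count]
  sort(setNames(as.integer(tab), names(tab)))
}

# oriented vertex set (both spellings of every canonical k-mer)
r_oriented <- function(canon) unique(c(canon, unname(r_revcomp(canon))))

# explicit adjacency by pairwise overlap comparison
r_adjacency <- function(canon) {
  vs <- r_oriented(canon)
  k <- nchar(vs[1])
  succ <- setNames(vector("list", length(vs)), vs)
  for (a in vs) {
    hits <- vs[substr(vs, 1, k - 1) == substr(a, 2, k)]
    succ[[a]] <- hits
  }
  succ
}

# blunt-end fraction by brute force: a canonical vertex is blunt when its
# spelled orientation has no successor or no predecessor among vertices
r_blunt_fraction <- function(canon) {
  succ <- r_adjacency(canon)
  vs <- names(succ)
  pred_count <- function(v) {
    k <- nchar(v)
    sum(vapply(vs, function(a) substr(a, 2, k) == substr(v, 1, k - 1), TRUE))
  }
  blunt <- vapply(canon, function(v) {
    length(succ[[v]]) == 0 || pred_count(v) == 0
  }, TRUE)
  mean(blunt)
}

# maximal non-branching paths by brute force over the oriented graph.
# Oriented vertices v, w are chain-linked iff succ(v) == {w}, pred(w) == {v}
# and neither is palindromic; every vertex then has at most one in-link and
# one out-link, so chains are the paths of this matching (cycles handled
# separately). Each chain appears once per strand; deduplicate canonically.
r_unitigs <- function(canon, min_len = 1) {
  succ <- r_adjacency(canon)
  vs <- names(succ)
  k <- nchar(vs[1])
  pred <- setNames(vector("list", length(vs)), vs)
  for (a in vs) for (b in succ[[a]]) pred[[b]] <- c(pred[[b]], a)
  is_pal <- vapply(vs, function(v) unname(r_revcomp(v)) == v, TRUE)
  out_link <- setNames(rep(NA_character_, length(vs)), vs)
  in_link <- setNames(rep(NA_character_, length(vs)), vs)
  for (v in vs) {
    if (is_pal[[v]] || length(succ[[v]]) != 1) next
    w <- succ[[v]][1]
    if (is_pal[[w]] || length(pred[[w]]) != 1) next
    out_link[[v]] <- w
    in_link[[w]] <- v
  }
  spell <- function(chain) {
    paste0(chain[1], paste(substr(chain[-1], k, k), collapse = ""))
  }
  out <- character(0)
  emitted <- character(0)
  emit <- function(chain) {
    seq <- spell(chain)
    key <- min(seq, unname(r_revcomp(seq)))
    if (!(key %in% emitted) && nchar(key) >= min_len) {
      emitted <<- c(emitted, key)
      out <<- c(out, key)
    }
    chain
  }
  done <- setNames(rep(FALSE, length(vs)), vs)
  for (v in vs) {
    if (done[[v]] || !is.na(in_link[[v]])) next # chain starts have no in-link
    chain <- v
    cur <- v
    while (!is.na(out_link[[cur]])) {
      cur <- out_link[[cur]]
      chain <- c(chain, cur)
    }
    done[chain] <- TRUE
    emit(chain)
  }
  # leftover vertices sit on pure cycles; open at the minimal canonical k-mer
  for (v0c in sort(unique(r_canon(vs[!done])))) {
    if (done[[v0c]]) next
    chain <- v0c
    cur <- v0c
    while (!is.na(out_link[[cur]]) && out_link[[cur]] != chain[1]) {
      cur <- out_link[[cur]]
      chain <- c(chain, cur)
    }
    done[chain] <- TRUE
    done[unname(r_revcomp(chain))] <- TRUE
    emit(chain)
  }
  sort(out)
}

# exhaustive DFS path enumeration over an exact canonical k-mer set
r_all_paths <- function(start, goal, canon, max_steps) {
  k <- nchar(start)
  set <- new.env(parent = emptyenv())
  for (v in canon) assign(v, TRUE, envir = set)
  has <- function(s) exists(min(s, unname(r_revcomp(s))), envir = set)
  paths <- character(0)
  walk <- function(path) {
    cur <- substr(path, nchar(path) - k + 1, nchar(path))
    if (cur == goal) {
      paths <<- c(paths, path)
      return(invisible())
    }
    if (nchar(path) - k >= max_steps) return(invisible())
    for (b in c("A", "C", "G", "T")) {
      nxt <- paste0(substr(cur, 2, k), b)
      if (has(nxt)) walk(paste0(path, b))
    }
  }
  # do not terminate on the start k-mer itself
  cur <- start
  for (b in c("A", "C", "G", "T")) {
    nxt <- paste0(substr(cur, 2, k), b)
    if (has(nxt)) walk(paste0(start, b))
  }
  sort(paths)
}

# deterministic random DNA for fixtures
r_random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# error-free tiling reads across a (possibly circular) sequence
r_tile_reads <- function(seq, read_len = 100, step = 5, circular = FALSE) {
  s <- if (circular) paste0(seq, substr(seq, 1, read_len - 1)) else seq
  starts <- seq(1, nchar(s) - read_len + 1, by = step)
  substring(s, starts, starts + read_len - 1)
}
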