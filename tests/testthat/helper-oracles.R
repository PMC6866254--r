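# Independent oracles and small generators used across the suite.

# connected components of the >= threshold graph by breadth-first search,
# labeled in ascending order of each component's smallest member ID
oracle_components <- function(m, threshold = 0.75) {
  n <- nrow(m)
  ids <- rownames(m)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(m[i, ] >= threshold & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  smallest <- vapply(seq_len(cur), function(k) sort(ids[comp == k])[1], "")
  relabel <- match(seq_len(cur), order(smallest))
  stats::setNames(relabel[comp], ids)
}

random_identity_matrix <- function(n) {
  m <- matrix(stats::runif(n * n), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  dimnames(m) <- list(sprintf("S%02d", seq_len(n)), sprintf("S%02d", seq_len(n)))
  m
}

# naive UPGMA returning the cophenetic (merge-height) matrix
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(d))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# draw a random structurally valid gene-name object
random_gene_name <- function() {
  grp <- sample(c("V", "D", "J", "C"), 1)
  dup <- sample(c(TRUE, FALSE), 1)
  if (grp == "V") {
    if (stats::runif(1) < 0.1)
      return(gene_name("V", subgroup = sample(30, 1), duplicated = dup,
                       provisional = TRUE, s_number = sample(20, 1)))
    return(gene_name("V", subgroup = sample(30, 1), duplicated = dup,
                     position = sample(200, 1)))
  }
  if (grp == "C") {
    iso <- sample(c("M", "Delta", "T"), 1)
    return(gene_name("C", isotype = iso, duplicated = dup,
                     subgroup = if (iso == "T") sample(9, 1) else NA_integer_))
  }
  tag <- if (stats::runif(1) < 0.5) paste0("T", sample(9, 1)) else NA_character_
  if (grp == "D" && is.na(tag) && stats::runif(1) < 0.3)
    return(gene_name("D", duplicated = dup, position = sample(30, 1)))
  gene_name(grp, duplicated = dup, cluster_index = sample(15, 1), c_tag = tag)
}

# amino-acid V-REGION with an exact framework architecture
make_vaa <- function(c1 = 12, c2 = 10) {
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  pick <- function(n, exclude = c("W", "C"))
    paste(sample(setdiff(aa20, exclude), n, replace = TRUE), collapse = "")
  paste0(pick(22), "C", pick(3),                 # FR1, C at 23
         pick(c1),                               # CDR1
         pick(2), "W", pick(14),                 # FR2, W at 3rd residue
         pick(c2),                               # CDR2
         pick(23), "V", pick(14), "C")           # FR3, hydrophobic 89, C 104
}

fixture <- function(name) {
  path <- system.file("extdata", name, package = "salmigh")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", name)
  path
}
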