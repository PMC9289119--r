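# shared fixtures, built in code

# small long-format census with known per-visit counts
make_counts <- function(df = NULL) {
  if (is.null(df)) {
    df <- expand.grid(point = c("p1", "p2"), visit = 1:2,
                      species = c("sA", "sB"), stringsAsFactors = FALSE)
    df$count <- c(3, 0, 5, 0,   # sA: p1 visits (3,5); p2 (0,0)
                  4, 2, 4, 2)   # sB: p1 visits (4,4); p2 (2,2)
  }
  df$transect <- "t1"
  df
}

# habitat table over the 7 aggregated classes; rows sum to 1
make_habitat <- function(comp) {
  stopifnot(is.matrix(comp))
  colnames(comp) <- aggregated_classes7[seq_len(ncol(comp))]
  data.frame(point = paste0("p", seq_len(nrow(comp))), comp,
             stringsAsFactors = FALSE)
}

# binary preference matrix over the 15 source classes
make_prefs <- function(rows) {
  m <- matrix(0L, length(rows), length(preference_classes15),
              dimnames = list(names(rows), preference_classes15))
  for (i in seq_along(rows)) m[i, rows[[i]]] <- 1L
  m
}

# random PSD covariance with species dimnames (via a random tree)
random_vcv <- function(n) {
  tr <- ape::rtree(n)
  tr$tip.label <- sprintf("s%02d", seq_len(n))
  brownian_vcv(tr)
}

# independent path-traversal oracle for the Brownian VCV: for every tip pair,
# walk root->tip paths and sum the shared edge lengths
vcv_path_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  parent <- integer(ntip + tree$Nnode)
  plen <- numeric(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(node) {
    nodes <- integer(0)
    while (node != root) {
      nodes <- c(nodes, node)
      node <- parent[node]
    }
    nodes
  }
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(ntip), path_to_root)
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    shared <- intersect(paths[[i]], paths[[j]])
    V[i, j] <- sum(plen[shared])
  }
  if (!is.null(tree$root.edge)) V <- V + tree$root.edge
  V
}

# whitening oracle for GLS: eigendecompose V, transform by V^(-1/2), run lm()
gls_whitening_oracle <- function(X, y, V) {
  e <- eigen(V, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(e$values)) %*% t(e$vectors)
  Xw <- W %*% X
  yw <- as.vector(W %*% y)
  fit <- lm(yw ~ Xw - 1)
  beta <- unname(coef(fit))
  n <- length(y)
  rss <- sum(residuals(fit)^2)
  s2 <- rss / n
  ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(e$values)) + n)
  list(beta = beta, logLik = ll, sigma2 = s2)
}

# independently coded full model averaging (the stated weight/SE formulas),
# written against plain lists rather than fit objects
average_oracle <- function(betas, ses, dfs, aics, delta_cut = 2) {
  delta <- aics - min(aics)
  keep <- delta < delta_cut
  betas <- betas[keep]; ses <- ses[keep]; dfs <- dfs[keep]
  w <- exp(-delta[keep] / 2); w <- w / sum(w)
  terms <- unique(unlist(lapply(betas, names)))
  res <- sapply(terms, function(j) {
    b <- sapply(betas, function(x) if (j %in% names(x)) x[[j]] else 0)
    s <- sapply(ses, function(x) if (j %in% names(x)) x[[j]] else 0)
    bbar <- sum(w * b)
    se <- sum(w * sqrt(s^2 + (b - bbar)^2))
    sa <- s * qt(0.975, dfs) / qnorm(0.975)
    adj <- sum(w * sqrt(sa^2 + (b - bbar)^2))
    c(estimate = bbar, se = se, adj_se = adj)
  })
  t(res)
}
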