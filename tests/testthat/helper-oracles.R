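# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: the alignment oracle enumerates
# alignments recursively, the shell oracle uses scalar double loops, and
# the superposition oracle is a generic numeric minimizer.

data("BLOSUM62", package = "Biostrings", envir = environment())

coords_of <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

# enumerate every global alignment of two short sequences, score with
# BLOSUM62 + affine gaps, and return the identity of the best-scoring
# alignment under the requested denominator
oracle_best_identity <- function(a, b, denominator = "alignment_columns",
                                 gap_open = 10, gap_ext = 0.5) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$idents <- numeric(0)
  recurse <- function(i, j, score, matches, cols, state) {
    if (i > length(a) && j > length(b)) {
      ident <- switch(denominator,
        alignment_columns = matches / cols,
        shorter_sequence = matches / min(length(a), length(b))
      )
      if (score > best$score + 1e-9) {
        best$score <- score
        best$idents <- ident
      } else if (abs(score - best$score) <= 1e-9) {
        best$idents <- c(best$idents, ident)
      }
      return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      recurse(i + 1, j + 1, score + BLOSUM62[a[i], b[j]],
              matches + (a[i] == b[j]), cols + 1, "m")
    }
    if (i <= length(a)) {
      pen <- if (state == "ga") gap_ext else gap_open + gap_ext
      recurse(i + 1, j, score - pen, matches, cols + 1, "ga")
    }
    if (j <= length(b)) {
      pen <- if (state == "gb") gap_ext else gap_open + gap_ext
      recurse(i, j + 1, score - pen, matches, cols + 1, "gb")
    }
  }
  recurse(1, 1, 0, 0, 0, "m")
  max(best$idents)
}

# shell counts by scalar double loops over every atom pair
oracle_shell_counts <- function(receptor, p, radius = 8,
                                cofactor_resname = "NAP") {
  acidic <- c("ASP", "GLU"); basic <- c("LYS", "ARG")
  sub <- p$substrate_atoms
  sub <- sub[!(sub$element %in% c("H", "D")), ]
  prot <- receptor[receptor$record == "ATOM" &
                     receptor$resname != cofactor_resname &
                     !(receptor$element %in% c("H", "D")), ]
  keys <- unique(paste(prot$chain, prot$resid))
  n_acidic <- 0L; n_basic <- 0L; his <- FALSE
  for (k in keys) {
    rows <- prot[paste(prot$chain, prot$resid) == k, ]
    mind <- Inf
    for (i in seq_len(nrow(rows))) {
      for (j in seq_len(nrow(sub))) {
        d <- sqrt((rows$x[i] - sub$x[j])^2 + (rows$y[i] - sub$y[j])^2 +
                    (rows$z[i] - sub$z[j])^2)
        if (d < mind) mind <- d
      }
    }
    if (mind <= radius) {
      rn <- rows$resname[1]
      rn <- c(HID = "HIS", HIE = "HIS", HIP = "HIS", ASH = "ASP",
              GLH = "GLU", LYN = "LYS")[rn] %||% rn
      if (rn %in% acidic) n_acidic <- n_acidic + 1L
      if (rn %in% basic) n_basic <- n_basic + 1L
      if (rn == "HIS") his <- TRUE
    }
  }
  list(n_acidic = n_acidic, n_basic = n_basic, n_his = as.integer(his))
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# minimum RMSD over rigid motions found by a generic numeric minimizer
# (Euler angles + translation), independent of the SVD route
oracle_min_rmsd <- function(mobile, reference) {
  obj <- function(par) {
    cx <- cos(par[1]); sx <- sin(par[1])
    cy <- cos(par[2]); sy <- sin(par[2])
    cz <- cos(par[3]); sz <- sin(par[3])
    rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
    ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
    rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
    rot <- rz %*% ry %*% rx
    fitted <- sweep(mobile %*% t(rot), 2, par[4:6], "+")
    sqrt(mean(rowSums((fitted - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.8, 1, -1, 2),
                     c(-1, 1, -2, 0, 0, 0), c(2, 0.2, -0.5, -2, 1, 0))) {
    fit <- optim(start, obj, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2))
  )
}
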