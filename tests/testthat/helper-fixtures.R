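# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no binary fixtures.

# -- tiny hand-written PDB text ------------------------------------------

toy_pdb_text <- function() {
  c("CRYST1   47.500   67.000  110.300  90.00  90.00  90.00 P 21 21 21    4",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.762   7.096  -4.999  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.155   7.773  -5.951  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      10.522   6.329  -4.132  1.00  0.00           C",
    "ATOM      6  N   GLY A   2      13.266   7.217  -3.775  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2      14.353   8.142  -3.466  1.00  0.00           C",
    "ATOM      8  C   GLY A   2      15.566   7.881  -4.343  1.00  0.00           C",
    "ATOM      9  O   GLY A   2      16.425   7.060  -4.003  1.00  0.00           O",
    "TER      10      GLY A   2",
    "END")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_text(), path)
  path
}

# PDB with altlocs, waters, a het group and two chains, for parsing rules
toy_pdb_mixed <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  N   SER A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA ASER A  10       1.500   0.000   0.000  0.50  0.00           C",
    "ATOM      3  CA BSER A  10       1.600   0.100   0.000  0.50  0.00           C",
    "ATOM      4  C   SER A  10       2.000   1.400   0.000  1.00  0.00           C",
    "ATOM      5  O   SER A  10       1.400   2.500   0.000  1.00  0.00           O",
    "ATOM      6  OG  SER A  10       2.100  -1.100   0.900  1.00  0.00           O",
    "ATOM      7  H   SER A  10       0.100   0.900   0.100  1.00  0.00           H",
    "TER       8      SER A  10",
    "ATOM      9  N   VAL B   5       5.000   5.000   5.000  1.00  0.00           N",
    "ATOM     10  CA  VAL B   5       6.500   5.000   5.000  1.00  0.00           C",
    "HETATM   11  O   HOH B 101       9.000   9.000   9.000  1.00  0.00           O",
    "HETATM   12  O   HOH B 102       9.500   9.500   9.000  1.00  0.00           O",
    "HETATM   13 ZN    ZN B 201       8.000   2.000   3.000  1.00  0.00          ZN",
    "END"), path)
  path
}

# -- coordinate helpers ---------------------------------------------------

model_xyz <- function(model) unname(as.matrix(model$atoms[, c("x", "y", "z")]))

transform_model <- function(model, tr) {
  xyz <- apply_transform(tr, as.matrix(model$atoms[, c("x", "y", "z")]))
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# -- brute-force contact oracle (all-pairs, O(N^2)) -----------------------

brute_contact_edges <- function(assembly, cutoff) {
  at <- as.data.frame(assembly)
  at <- at[!at$is_het & !(at$resid %in% c("HOH", "WAT")) &
             toupper(at$elesy) != "H", , drop = FALSE]
  xyz <- as.matrix(at[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  hit <- hit[at$subunit[hit[, 1]] != at$subunit[hit[, 2]], , drop = FALSE]
  if (!nrow(hit)) {
    return(data.frame(index_a = integer(0), index_b = integer(0),
                      segment_a = character(0), segment_b = character(0),
                      n_atom_pairs = integer(0), min_dist_A = numeric(0)))
  }
  i <- hit[, 1]; j <- hit[, 2]; dd <- d[hit]
  both <- data.frame(index_a = c(at$subunit[i], at$subunit[j]),
                     index_b = c(at$subunit[j], at$subunit[i]),
                     segment_a = c(at$segment[i], at$segment[j]),
                     segment_b = c(at$segment[j], at$segment[i]),
                     dist = c(dd, dd))
  key <- paste(both$index_a, both$index_b, both$segment_a, both$segment_b,
               sep = "|")
  out <- data.frame(do.call(rbind, strsplit(sort(unique(key)), "|", fixed = TRUE)),
                    stringsAsFactors = FALSE)
  names(out) <- c("index_a", "index_b", "segment_a", "segment_b")
  out$index_a <- as.integer(out$index_a); out$index_b <- as.integer(out$index_b)
  ord_key <- paste(out$index_a, out$index_b, out$segment_a, out$segment_b, sep = "|")
  out$n_atom_pairs <- as.integer(tapply(both$dist, key, length)[ord_key])
  out$min_dist_A <- as.numeric(tapply(both$dist, key, min)[ord_key])
  out <- out[order(out$index_a, out$index_b, out$segment_a, out$segment_b), ]
  rownames(out) <- NULL
  out
}

normalize_edges <- function(e) {
  e <- as.data.frame(e)[, c("index_a", "index_b", "segment_a", "segment_b",
                            "n_atom_pairs", "min_dist_A")]
  e <- e[order(e$index_a, e$index_b, e$segment_a, e$segment_b), ]
  rownames(e) <- NULL
  e
}

# -- brute-force global affine alignment oracle ---------------------------
# Enumerates every monotone alignment path of two short sequences and scores
# it with a substitution matrix and affine gap costs (open + len * extend,
# end gaps penalized). Exponential; only for sequences of length <= 8.

brute_force_align_score <- function(sa, sb, smat, open = 10, extend = 0.5) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  n <- length(a); m <- length(b)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i == n && j == m) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i < n && j < m)
      rec(i + 1, j + 1, score + smat[a[i + 1], b[j + 1]], "M")
    if (i < n)
      rec(i + 1, j, score - extend - if (prev == "D") 0 else open, "D")
    if (j < m)
      rec(i, j + 1, score - extend - if (prev == "I") 0 else open, "I")
  }
  rec(0, 0, 0, "start")
  best
}

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
}

# -- network fetch for deposited-entry checks -----------------------------
# These checks require small downloads; they fail cleanly when the host is
# unreachable.

fetch_rcsb <- function(id, format = "pdb") {
  url <- sprintf("https://files.rcsb.org/download/%s.%s", toupper(id), format)
  dest <- file.path(tempdir(), paste0(toupper(id), ".", format))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  old <- options(timeout = 30); on.exit(options(old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download ", url)
  }
  dest
}

fetch_uniprot <- function(acc) {
  url <- sprintf("https://rest.uniprot.org/uniprotkb/%s.fasta", acc)
  dest <- file.path(tempdir(), paste0(acc, ".fasta"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  old <- options(timeout = 30); on.exit(options(old))
  ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE, mode = "wb") == 0,
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("could not download ", url)
  }
  dest
}
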