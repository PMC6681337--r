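#' Subunit coordinate model
#'
#' The package represents one subunit (one polypeptide chain) as a flat atom
#' table plus a set of named segment annotations. The atom table follows the
#' conventions of crystallographic model files: author residue numbering
#' (1-based, inclusive ranges), optional insertion codes, 3-letter residue
#' names, and per-atom element symbols. Segments carry the domain
#' nomenclature of flagellar axial proteins: the N- and C-terminal D0
#' helices (\code{D0N}, \code{D0C}), the extended l-stretch arm
#' (\code{L_STRETCH}), and the outer domains \code{D1}, \code{D2}.
#'
#' @param atoms data.frame with columns \code{eleno} (atom serial),
#'   \code{elety} (atom name), \code{resid} (3-letter residue name),
#'   \code{resno} (author residue number), \code{insert} (insertion code,
#'   \code{""} if none), \code{alt} (alternate location id, \code{""} if
#'   none), \code{x}, \code{y}, \code{z} (Angstrom), \code{o} (occupancy),
#'   \code{b} (B factor), \code{elesy} (element symbol), \code{is_het}
#'   (logical, HETATM record).
#' @param chain_id single-character chain identifier.
#' @param segments named list mapping segment name to a numeric vector
#'   \code{c(start, end)} or a 2-column matrix of inclusive residue-number
#'   ranges (one row per range).
#' @return An object of class \code{subunit_model}.
#' @export
subunit_model <- function(atoms, chain_id = "A", segments = list()) {
  need <- c("eleno", "elety", "resid", "resno", "insert", "alt",
            "x", "y", "z", "o", "b", "elesy", "is_het")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms)) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("atom coordinates must be finite")
    if (any(!nzchar(atoms$elesy)))
      stop("element symbols must be non-empty")
  }
  segments <- normalize_segments(segments)
  check_segments_disjoint(segments)
  m <- structure(list(chain_id = chain_id,
                      atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                      segments = segments),
                 class = "subunit_model")
  rng <- residue_range(m)
  for (nm in names(segments)) {
    s <- segments[[nm]]
    if (nrow(s) && !is.null(rng) &&
        (min(s[, 1]) < rng[1] || max(s[, 2]) > rng[2]))
      stop("segment '", nm, "' extends outside the residue span ",
           rng[1], "-", rng[2])
  }
  m
}

normalize_segments <- function(segments) {
  lapply(segments, function(s) {
    if (is.null(dim(s))) s <- matrix(as.numeric(s), ncol = 2, byrow = TRUE)
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    colnames(s) <- c("start", "end")
    if (any(s[, 2] < s[, 1])) stop("segment range with end < start")
    s
  })
}

check_segments_disjoint <- function(segments) {
  if (length(segments) < 1) return(invisible(TRUE))
  rngs <- do.call(rbind, unname(segments))
  if (is.null(rngs) || nrow(rngs) < 2) return(invisible(TRUE))
  covered <- unlist(apply(rngs, 1L, function(r) seq(r[1], r[2]), simplify = FALSE))
  if (anyDuplicated(covered))
    stop("segment ranges overlap at residue(s) ",
         paste(unique(covered[duplicated(covered)]), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.subunit_model <- function(x, ...) {
  rng <- residue_range(x)
  cat("subunit_model: chain", x$chain_id, "|",
      length(protein_resnos(x)), "protein residues",
      if (!is.null(rng)) paste0("(", rng[1], "-", rng[2], ")"), "|",
      nrow(x$atoms), "atoms\n")
  if (length(x$segments)) {
    seg <- vapply(names(x$segments), function(nm) {
      s <- x$segments[[nm]]
      paste(apply(s, 1, function(r) paste0(r[1], "-", r[2])), collapse = ",")
    }, "")
    cat("  segments:", paste(names(seg), seg, sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Protein (polymer) residue numbers of a model
#' @param model a \code{subunit_model}.
#' @return sorted unique residue numbers of non-water, non-het residues.
#' @export
protein_resnos <- function(model) {
  a <- model$atoms
  sort(unique(a$resno[!a$is_het & !is_water_resid(a$resid)]))
}

residue_range <- function(model) {
  r <- protein_resnos(model)
  if (!length(r)) return(NULL)
  c(min(r), max(r))
}

is_water_resid <- function(resid) resid %in% c("HOH", "WAT", "DOD")

#' Segment name of each residue number
#' @param model a \code{subunit_model}.
#' @param resno vector of residue numbers.
#' @return character vector of segment names; \code{"UNASSIGNED"} where no
#'   segment covers the residue.
#' @export
segment_of <- function(model, resno) {
  out <- rep("UNASSIGNED", length(resno))
  for (nm in names(model$segments)) {
    s <- model$segments[[nm]]
    hit <- rep(FALSE, length(resno))
    for (i in seq_len(nrow(s))) hit <- hit | (resno >= s[i, 1] & resno <= s[i, 2])
    out[hit] <- nm
  }
  out
}

#' Coordinates of selected atoms
#'
#' @param model a \code{subunit_model}.
#' @param atom_name atom name to select (e.g. \code{"CA"}); \code{NULL} for
#'   all heavy atoms.
#' @param resno optional residue numbers to restrict to.
#' @return numeric matrix (n x 3) with rownames set to residue numbers when
#'   one atom per residue is selected.
#' @export
model_coords <- function(model, atom_name = "CA", resno = NULL) {
  a <- model$atoms
  keep <- !a$is_het & !is_water_resid(a$resid) & toupper(a$elesy) != "H"
  if (!is.null(atom_name)) keep <- keep & a$elety == atom_name
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  m <- as.matrix(a[keep, c("x", "y", "z")])
  if (!is.null(atom_name)) rownames(m) <- paste0(a$resno[keep], a$insert[keep])
  m
}

#' One-letter amino-acid sequence of a model
#' @param model a \code{subunit_model}.
#' @return single string in one-letter code; unknown residue types become
#'   \code{X}.
#' @export
model_sequence <- function(model) {
  a <- model$atoms
  keep <- !a$is_het & !is_water_resid(a$resid)
  key <- paste(a$resno[keep], a$insert[keep])
  resid <- a$resid[keep][!duplicated(key)]
  ord <- order(a$resno[keep][!duplicated(key)])
  paste(aa_three_to_one(resid[ord]), collapse = "")
}

aa_three_to_one <- function(x) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
           MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
           TYR = "Y", VAL = "V", MSE = "M")
  out <- tab[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

# ---- reading -------------------------------------------------------------

#' Read a structure file into subunit models
#'
#' Parses a PDB or mmCIF file into one \code{subunit_model} per chain.
#' Alternate locations are reduced to the first conformer (lexicographically
#' smallest non-blank altloc id), hydrogens are dropped (downstream contact
#' analysis is heavy-atom), waters and other heteroatoms are preserved in the
#' atom table but excluded from protein counts. Unit-cell parameters and the
#' space-group string from the header are attached as attributes when
#' present.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"}, or \code{"cif"}.
#' @return named list of \code{subunit_model} (one per chain, in file
#'   order), with attributes \code{cell} (named numeric a, b, c, alpha,
#'   beta, gamma) and \code{space_group} when the header carries them.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly"))
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$chain[is.na(at$chain)] <- " "
  # first-conformer selection: keep blank altloc plus, per residue+atom, the
  # lexicographically smallest altloc id
  if (any(nzchar(at$alt))) {
    key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    ord <- order(key, at$alt)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid, at$elety)), ,
             drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }
  at <- at[toupper(ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                          guess_element(at$elety), at$elesy)) != "H", ,
           drop = FALSE]
  at$elesy <- ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                     guess_element(at$elety), at$elesy)
  models <- lapply(split(seq_len(nrow(at)), factor(at$chain, unique(at$chain))),
                   function(i) {
    a <- at[i, , drop = FALSE]
    subunit_model(data.frame(eleno = a$eleno, elety = a$elety, resid = a$resid,
                             resno = a$resno, insert = a$insert, alt = a$alt,
                             x = a$x, y = a$y, z = a$z,
                             o = ifelse(is.na(a$o), 1, a$o),
                             b = ifelse(is.na(a$b), 0, a$b),
                             elesy = a$elesy, is_het = a$type == "HETATM",
                             stringsAsFactors = FALSE),
                  chain_id = a$chain[1])
  })
  names(models) <- vapply(models, function(m) m$chain_id, "")
  hdr <- read_header_metadata(path, format)
  attr(models, "cell") <- hdr$cell
  attr(models, "space_group") <- hdr$space_group
  models
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", toupper(elety))
  two <- substr(e, 1, 2)
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "SE", "CL", "BR", "NA", "CA "),
         two, substr(e, 1, 1))
}

read_header_metadata <- function(path, format) {
  out <- list(cell = NULL, space_group = NULL)
  lines <- readLines(path, n = 2000L, warn = FALSE)
  if (format == "pdb") {
    cr <- grep("^CRYST1", lines, value = TRUE)
    if (length(cr)) {
      f <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
             substr(cr[1], 25, 33), substr(cr[1], 34, 40), substr(cr[1], 41, 47),
             substr(cr[1], 48, 54))))
      if (all(is.finite(f))) {
        names(f) <- c("a", "b", "c", "alpha", "beta", "gamma")
        out$cell <- f
      }
      sg <- trimws(substr(cr[1], 56, 66))
      if (nzchar(sg)) out$space_group <- sg
    }
  } else {
    gv <- function(tag) {
      ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
      if (!length(ln)) return(NA_character_)
      trimws(sub(paste0("^", tag, "\\s+"), "", ln[1]))
    }
    cl <- suppressWarnings(as.numeric(c(gv("_cell.length_a"), gv("_cell.length_b"),
            gv("_cell.length_c"), gv("_cell.angle_alpha"), gv("_cell.angle_beta"),
            gv("_cell.angle_gamma"))))
    if (all(is.finite(cl))) {
      names(cl) <- c("a", "b", "c", "alpha", "beta", "gamma")
      out$cell <- cl
    }
    sg <- gv("_symmetry.space_group_name_H-M")
    if (!is.na(sg)) out$space_group <- gsub("^['\"]|['\"]$", "", sg)
  }
  out
}

# ---- writing -------------------------------------------------------------

pdb_chain_alphabet <- c(LETTERS, letters, as.character(0:9))

#' Write subunit models to a structure file
#'
#' Writes one or more \code{subunit_model}s (or an \code{axial_assembly}) to
#' PDB or mmCIF. The PDB dialect is limited to 62 chains by its one-character
#' chain-id alphabet; larger assemblies must be written as mmCIF.
#'
#' @param models a \code{subunit_model}, a list of them, or an
#'   \code{axial_assembly}.
#' @param path output file path.
#' @param format \code{"pdb"} or \code{"cif"}; default inferred from the
#'   extension.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(models, path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "cif", mmcif = "cif",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  models <- as_model_list(models)
  if (format == "pdb" && length(models) > length(pdb_chain_alphabet))
    stop("assembly has ", length(models), " chains; the PDB chain-id ",
         "alphabet holds at most ", length(pdb_chain_alphabet),
         " - write mmCIF instead")
  if (format == "pdb") write_pdb_models(models, path) else write_cif_models(models, path)
  invisible(path)
}

as_model_list <- function(models) {
  if (inherits(models, "axial_assembly"))
    models <- lapply(models$subunits, `[[`, "model")
  if (inherits(models, "subunit_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "subunit_model")))
  models
}

write_pdb_models <- function(models, path) {
  ats <- lapply(seq_along(models), function(i) {
    a <- models[[i]]$atoms
    a$chain <- models[[i]]$chain_id
    a
  })
  a <- do.call(rbind, ats)
  if (any(abs(c(a$x, a$y, a$z)) >= 10000))
    stop("coordinates exceed the PDB fixed-width field range (|x| < 10000)")
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   type = ifelse(a$is_het, "HETATM", "ATOM"),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, NA),
                   alt = ifelse(nzchar(a$alt), a$alt, NA),
                   o = a$o, b = a$b, elesy = a$elesy, chainter = TRUE)
  invisible(path)
}

# Minimal atom_site mmCIF writer (no installed R package writes mmCIF).
write_cif_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("data_axialkit",
               "#",
               "loop_",
               "_atom_site.group_PDB",
               "_atom_site.id",
               "_atom_site.type_symbol",
               "_atom_site.label_atom_id",
               "_atom_site.label_alt_id",
               "_atom_site.label_comp_id",
               "_atom_site.label_asym_id",
               "_atom_site.label_entity_id",
               "_atom_site.label_seq_id",
               "_atom_site.pdbx_PDB_ins_code",
               "_atom_site.Cartn_x",
               "_atom_site.Cartn_y",
               "_atom_site.Cartn_z",
               "_atom_site.occupancy",
               "_atom_site.B_iso_or_equiv",
               "_atom_site.pdbx_formal_charge",
               "_atom_site.auth_seq_id",
               "_atom_site.auth_comp_id",
               "_atom_site.auth_asym_id",
               "_atom_site.auth_atom_id",
               "_atom_site.pdbx_PDB_model_num"), con)
  serial <- 0L
  for (mi in seq_along(models)) {
    m <- models[[mi]]
    a <- m$atoms
    if (!nrow(a)) next
    serials <- serial + seq_len(nrow(a))
    serial <- serial + nrow(a)
    writeLines(sprintf("%s %d %s %s %s %s %s %d %d %s %.17g %.17g %.17g %.3f %.3f ? %d %s %s %s 1",
                       ifelse(a$is_het, "HETATM", "ATOM"), serials, a$elesy,
                       a$elety, ifelse(nzchar(a$alt), a$alt, "."), a$resid,
                       m$chain_id, mi, seq_len(nrow(a)),
                       ifelse(nzchar(a$insert), a$insert, "?"),
                       a$x, a$y, a$z, a$o, a$b,
                       a$resno, a$resid, m$chain_id, a$elety), con)
  }
  writeLines("#", con)
  invisible(path)
}

# ---- counting ------------------------------------------------------------

#' Count model contents
#'
#' Tallies polymer residues, waters, and non-hydrogen polymer atoms across a
#' set of chains, in the convention of crystallographic model-content tables:
#' waters are residues named HOH/WAT; other het groups are excluded from the
#' protein counts.
#'
#' @param models a \code{subunit_model} or list of them (e.g. from
#'   \code{\link{read_structure}}).
#' @return list with \code{protein_residues}, \code{waters},
#'   \code{protein_atoms}.
#' @export
count_contents <- function(models) {
  models <- as_model_list(models)
  pr <- 0L; wa <- 0L; pa <- 0L
  for (m in models) {
    a <- m$atoms
    water <- is_water_resid(a$resid)
    poly <- !a$is_het & !water
    heavy <- toupper(a$elesy) != "H"
    pr <- pr + length(unique(paste(a$resno, a$insert)[poly]))
    wa <- wa + length(unique(paste(a$resno, a$insert)[water]))
    pa <- pa + sum(poly & heavy)
  }
  list(protein_residues = pr, waters = wa, protein_atoms = pa)
}
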