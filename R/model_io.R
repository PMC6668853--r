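#' Molecular system container
#'
#' The substrate of all simulation and substitution: an atom table,
#' coordinates, bond topology and special constraints (disulfide,
#' metal-ligand, peptide links created by substitution).
#'
#' @param atoms Tibble with columns `name`, `element`, `charge`,
#'   `mass`, `resname`, `chain`, `resno`, `x`, `y`, `z`. Residue
#'   numbers follow 1-based author numbering from the source PDB.
#' @param bonds Two-column integer matrix of 1-based atom index pairs.
#' @param special_constraints Optional tibble with columns `i`, `j`,
#'   `type` (`disulfide`, `metal` or `peptide`).
#' @return An object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, bonds = NULL, special_constraints = NULL) {
  req <- c("name", "element", "charge", "mass", "resname", "chain", "resno",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) == 0) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("coordinates must be finite")
  }
  if (is.null(bonds)) bonds <- matrix(integer(0), ncol = 2)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds) > 0) {
    if (any(bonds < 1 | bonds > nrow(atoms))) stop("bond index out of range")
    if (any(bonds[, 1] == bonds[, 2])) stop("self-bond in bond list")
    key <- paste(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
    if (anyDuplicated(key)) stop("duplicate bonds in bond list")
    bonds <- unique(cbind(pmin(bonds[, 1], bonds[, 2]),
                          pmax(bonds[, 1], bonds[, 2])))
  }
  if (is.null(special_constraints)) {
    special_constraints <- tibble::tibble(i = integer(), j = integer(),
                                          type = character())
  }
  structure(list(atoms = atoms, bonds = bonds,
                 special_constraints = tibble::as_tibble(special_constraints)),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  res <- unique(paste(x$atoms$chain, x$atoms$resno))
  cat("<molecular_system> ", nrow(x$atoms), " atoms, ", length(res),
      " residues, ", length(unique(x$atoms$chain)), " chain(s), ",
      nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Coordinate matrix of a system
#' @param system A [molecular_system()].
#' @return Numeric n x 3 matrix (Angstrom).
#' @export
system_coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a system
#' @param system A [molecular_system()].
#' @param coords Numeric n x 3 matrix.
#' @return The modified system.
#' @export
set_system_coords <- function(system, coords) {
  stopifnot(nrow(coords) == nrow(system$atoms))
  system$atoms$x <- coords[, 1]
  system$atoms$y <- coords[, 2]
  system$atoms$z <- coords[, 3]
  system
}

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, CU = 63.546, ZN = 65.38,
                     FE = 55.845, MG = 24.305, CA = 40.078, NA. = 22.99)

.element_vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                  P = 1.80, CU = 1.40, ZN = 1.39, FE = 1.40, MG = 1.73)

.mass_of <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

.guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("CU", "ZN", "FE", "MG", "CL", "BR"), two,
                substr(nm, 1, 1))
  out[out == ""] <- "C"
  out
}

# Distance-based bond inference: covalent pairs for all-atom models,
# consecutive-residue links for single-bead (C-alpha style) chains.
.infer_bonds <- function(atoms) {
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(coords)
  per_res <- table(paste(atoms$chain, atoms$resno))
  bonds <- list()
  if (max(per_res) == 1L) {
    # coarse-grained chain: bond successive residues in each chain
    for (ch in unique(atoms$chain)) {
      idx <- which(atoms$chain == ch)
      idx <- idx[order(atoms$resno[idx])]
      if (length(idx) < 2) next
      for (k in seq_len(length(idx) - 1)) {
        d <- sqrt(sum((coords[idx[k], ] - coords[idx[k + 1], ])^2))
        if (d < 5.0) bonds[[length(bonds) + 1L]] <- c(idx[k], idx[k + 1])
      }
    }
  } else {
    cut_heavy <- 1.95
    cut_h <- 1.25
    is_h <- atoms$element == "H"
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        lim <- if (is_h[i] || is_h[j]) cut_h else cut_heavy
        if (abs(coords[i, 1] - coords[j, 1]) > lim) next
        d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (d <= lim && d > 0.4) bonds[[length(bonds) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(bonds)) do.call(rbind, bonds) else matrix(integer(0), ncol = 2)
}

# Disulfide and metal-ligand links detected by distance, emitted as
# special constraints so the engine pins them with square wells.
.detect_special <- function(atoms) {
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  out <- list()
  sg <- which(atoms$element == "S" & atoms$resname %in% c("CYS", "CYX"))
  if (length(sg) > 1) {
    for (a in seq_along(sg)[-length(sg)]) {
      for (b in (a + 1):length(sg)) {
        d <- sqrt(sum((coords[sg[a], ] - coords[sg[b], ])^2))
        if (d < 2.5) {
          out[[length(out) + 1L]] <- tibble::tibble(i = sg[a], j = sg[b],
                                                    type = "disulfide")
        }
      }
    }
  }
  metals <- which(atoms$element %in% c("CU", "ZN", "FE", "MG"))
  ligands <- which(atoms$element %in% c("N", "O", "S"))
  for (m in metals) {
    for (l in ligands) {
      d <- sqrt(sum((coords[m, ] - coords[l, ])^2))
      if (d < 2.8) {
        out[[length(out) + 1L]] <- tibble::tibble(i = min(m, l), j = max(m, l),
                                                  type = "metal")
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else NULL
}

#' Read a PDB file into a molecular system
#'
#' Parses ATOM/HETATM records (via the bio3d reader), keeping alternate
#' location 'A' or blank, skipping waters by default, and preserving
#' author chain identifiers and residue numbers. Bonds are inferred by
#' distance (covalent cutoffs for all-atom files; consecutive-residue
#' links for single-bead chains) and disulfide / metal-ligand contacts
#' are recorded as special constraints.
#'
#' @param path PDB file path.
#' @param keep_waters Keep HOH/WAT residues? Default `FALSE`.
#' @return A [molecular_system()].
#' @export
read_pdb <- function(path, keep_waters = FALSE) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("unreadable PDB file: ",
                                           conditionMessage(e)))
  a <- pdb$atom
  keep <- a$alt %in% c("", "A", NA)
  if (!keep_waters) keep <- keep & !(a$resid %in% c("HOH", "WAT", "DOD"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0) stop("empty structure: no atoms after filtering")
  element <- ifelse(is.na(a$elesy) | a$elesy == "", .guess_element(a$elety),
                    toupper(a$elesy))
  atoms <- tibble::tibble(
    name = a$elety, element = element, charge = 0,
    mass = .mass_of(element),
    resname = a$resid, chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, x = a$x, y = a$y, z = a$z)
  bonds <- .infer_bonds(atoms)
  special <- .detect_special(atoms)
  molecular_system(atoms, bonds, special)
}

#' Write a molecular system to a PDB file
#'
#' @param system A [molecular_system()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path) {
  a <- system$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(system_coords(system))),
                   resno = a$resno, resid = a$resname, chain = a$chain,
                   elety = a$name, elesy = a$element)
  invisible(path)
}

## ---- residue templates -------------------------------------------------

#' Read a residue template file
#'
#' Template files carry three sections: `[atoms]` (name, element,
#' formal charge, and for side-chain atoms the three anchor atoms plus
#' bond length / angle / torsion internal coordinates, where the
#' torsion field may reference a chi variable as `chi1`, `chi2+120`,
#' ...), `[bonds]` (atom name pairs) and `[chi]` (the four atoms
#' defining each chi torsion).
#'
#' @param name Template name (e.g. `"SER"`, `"BMAA"`, `"LYS"`) resolved
#'   against the packaged template directory, or a path to a `.tmpl`
#'   file.
#' @return An object of class `residue_template`.
#' @export
residue_template <- function(name) {
  path <- if (file.exists(name)) name else {
    system.file("extdata", "templates", paste0(toupper(name), ".tmpl"),
                package = "stepfold")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("no template for residue '", name, "'")
  }
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  sec <- NA_character_
  atoms <- list(); bonds <- list(); chis <- list()
  resname <- toupper(sub("\\.tmpl$", "", basename(path)))
  for (ln in lines) {
    if (grepl("^\\[", ln)) { sec <- gsub("[][]", "", ln); next }
    f <- strsplit(ln, "\\s+")[[1]]
    if (identical(sec, "atoms")) {
      atoms[[length(atoms) + 1L]] <- tibble::tibble(
        name = f[1], element = f[2], charge = as.numeric(f[3]),
        anchor1 = ifelse(f[4] == "-", NA, f[4]),
        anchor2 = ifelse(f[5] == "-", NA, f[5]),
        anchor3 = ifelse(f[6] == "-", NA, f[6]),
        length = ifelse(f[7] == "-", NA, suppressWarnings(as.numeric(f[7]))),
        angle = ifelse(f[8] == "-", NA, suppressWarnings(as.numeric(f[8]))),
        torsion = ifelse(f[9] == "-", NA, f[9]))
    } else if (identical(sec, "bonds")) {
      bonds[[length(bonds) + 1L]] <- f[1:2]
    } else if (identical(sec, "chi")) {
      chis[[length(chis) + 1L]] <- f[1:4]
    }
  }
  atoms <- dplyr::bind_rows(atoms)
  atoms$mass <- .mass_of(atoms$element)
  structure(list(name = resname, atoms = atoms,
                 bonds = do.call(rbind, bonds), chi = chis,
                 n_chi = length(chis),
                 net_charge = sum(atoms$charge)),
            class = "residue_template")
}

#' @export
print.residue_template <- function(x, ...) {
  cat("<residue_template> ", x$name, ": ", nrow(x$atoms), " atoms, n_chi = ",
      x$n_chi, ", net charge ", sprintf("%+g", x$net_charge), "\n", sep = "")
  invisible(x)
}

#' The BMAA residue template
#'
#' beta-methylamino-L-alanine: a serine-sized backbone carrying a
#' CB--N(methylamino)--C(methyl) side chain with a protonated secondary
#' amine, hence two chi torsions and a net formal charge of +1.
#' Geometry uses standard amino-acid bond lengths and tetrahedral
#' angles.
#'
#' @return A `residue_template`.
#' @export
bmaa_template <- function() residue_template("BMAA")

# NeRF placement: position atom D given anchors A, B, C and internal
# coordinates (C-D bond length, B-C-D angle, A-B-C-D torsion, degrees).
.place_atom <- function(A, B, C, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("degenerate anchor geometry for atom placement")
  n <- n / nn
  m <- pracma_cross(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Resolve a template torsion spec ("chi1", "chi2+120", "-60", ...) to a
# numeric torsion given chi angle values.
.resolve_torsion <- function(spec, chi) {
  if (grepl("^chi", spec)) {
    m <- regmatches(spec, regexec("^chi([0-9]+)([+-][0-9.]+)?$", spec))[[1]]
    k <- as.integer(m[2])
    off <- if (nzchar(m[3])) as.numeric(m[3]) else 0
    if (k > length(chi)) stop("template references chi", k,
                              " but only ", length(chi), " provided")
    chi[k] + off
  } else {
    as.numeric(spec)
  }
}

# Build side-chain coordinates for a template given the four backbone
# anchor coordinates (named list N, CA, C, O) and chi angles.
.build_sidechain <- function(template, backbone, chi) {
  placed <- backbone
  sc <- template$atoms[!template$atoms$name %in% c("N", "CA", "C", "O"), ,
                       drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(sc))) {
    row <- sc[k, ]
    anchors <- c(row$anchor1, row$anchor2, row$anchor3)
    if (any(is.na(anchors)) || !all(anchors %in% names(placed))) {
      stop("template atom ", row$name, " has unresolvable anchors")
    }
    tor <- .resolve_torsion(row$torsion, chi)
    pos <- .place_atom(placed[[anchors[1]]], placed[[anchors[2]]],
                       placed[[anchors[3]]], row$length, row$angle, tor)
    placed[[row$name]] <- pos
    out[[row$name]] <- list(pos = pos, element = row$element,
                            charge = row$charge, mass = row$mass)
  }
  out
}

#' Substitute one residue by a template
#'
#' Deletes the side chain of the addressed residue, keeps its backbone
#' atoms and coordinates, rebuilds the new side chain from the
#' template's internal coordinates with every chi angle at its first
#' staggered value (+60 degrees), and regenerates peptide-bond
#' constraints to the sequence neighbours. Only the addressed chain is
#' touched.
#'
#' @param system A [molecular_system()].
#' @param chain Chain identifier.
#' @param seq Author residue number within the chain.
#' @param template A `residue_template` (or template name).
#' @param chi Optional chi angles (degrees) overriding the staggered
#'   default.
#' @return The modified [molecular_system()].
#' @export
substitute_residue <- function(system, chain, seq, template, chi = NULL) {
  if (is.character(template)) template <- residue_template(template)
  at <- system$atoms
  sel <- which(at$chain == chain & at$resno == seq)
  if (length(sel) == 0) {
    stop("residue not found: chain ", chain, " residue ", seq)
  }
  bb_names <- c("N", "CA", "C", "O")
  bb_idx <- sel[match(bb_names, at$name[sel])]
  if (any(is.na(bb_idx))) {
    stop("incomplete backbone at chain ", chain, " residue ", seq, ": missing ",
         paste(bb_names[is.na(match(bb_names, at$name[sel]))], collapse = ", "))
  }
  backbone <- stats::setNames(lapply(bb_idx, function(i)
    c(at$x[i], at$y[i], at$z[i])), bb_names)
  if (is.null(chi)) chi <- rep(60, template$n_chi)
  side <- .build_sidechain(template, backbone, chi)

  drop_idx <- setdiff(sel, bb_idx)          # old side chain
  keep <- setdiff(seq_len(nrow(at)), drop_idx)
  remap <- match(seq_len(nrow(at)), keep)   # old index -> new index
  new_at <- at[keep, , drop = FALSE]
  new_at$resname[remap[bb_idx]] <- template$name
  add <- dplyr::bind_rows(lapply(names(side), function(nm) {
    s <- side[[nm]]
    tibble::tibble(name = nm, element = s$element, charge = s$charge,
                   mass = s$mass, resname = template$name, chain = chain,
                   resno = seq, x = s$pos[1], y = s$pos[2], z = s$pos[3])
  }))
  # splice the new side chain right after the backbone O, preserving
  # residue order in the file
  ins <- remap[bb_idx[4]]
  n_new <- nrow(new_at)
  if (nrow(add) > 0) {
    new_at <- dplyr::bind_rows(new_at[seq_len(ins), ], add,
                               new_at[setdiff(seq_len(n_new), seq_len(ins)), ])
  }
  # rebuild indices: map kept old atoms to rows of new_at
  final_idx <- integer(n_new)
  final_idx[seq_len(ins)] <- seq_len(ins)
  if (n_new > ins) final_idx[(ins + 1):n_new] <- (ins + nrow(add) + 1):(nrow(new_at))
  old_to_new <- ifelse(is.na(remap), NA_integer_, final_idx[remap])
  side_idx <- stats::setNames(ins + seq_len(nrow(add)),
                              if (nrow(add)) add$name else character(0))

  # bonds: drop any touching the removed side chain, remap the rest
  b <- system$bonds
  if (nrow(b) > 0) {
    okrow <- !(b[, 1] %in% drop_idx | b[, 2] %in% drop_idx)
    b <- cbind(old_to_new[b[okrow, 1]], old_to_new[b[okrow, 2]])
  }
  tmpl_bonds <- template$bonds
  name_to_idx <- function(nm) {
    if (nm %in% names(side_idx)) side_idx[[nm]]
    else old_to_new[bb_idx[match(nm, bb_names)]]
  }
  extra <- if (!is.null(tmpl_bonds)) {
    t(apply(tmpl_bonds, 1, function(p) c(name_to_idx(p[1]), name_to_idx(p[2]))))
  } else NULL
  bonds <- rbind(b, extra)
  bonds <- bonds[!duplicated(paste(pmin(bonds[, 1], bonds[, 2]),
                                   pmax(bonds[, 1], bonds[, 2]))), , drop = FALSE]

  # special constraints: remap, drop those touching removed atoms,
  # regenerate peptide links to sequence neighbours
  sc <- system$special_constraints
  if (nrow(sc) > 0) {
    ok <- !(sc$i %in% drop_idx | sc$j %in% drop_idx)
    sc <- sc[ok, , drop = FALSE]
    sc$i <- old_to_new[sc$i]
    sc$j <- old_to_new[sc$j]
  }
  for (nb in c(-1, 1)) {
    nb_sel <- which(new_at$chain == chain & new_at$resno == seq + nb)
    if (length(nb_sel) == 0) next
    if (nb == -1) {
      ci <- nb_sel[new_at$name[nb_sel] == "C"]
      nj <- old_to_new[bb_idx[1]]
    } else {
      ci <- old_to_new[bb_idx[3]]
      nj <- nb_sel[new_at$name[nb_sel] == "N"]
    }
    if (length(ci) == 1 && length(nj) == 1 && !is.na(ci) && !is.na(nj)) {
      sc <- dplyr::bind_rows(sc, tibble::tibble(i = min(ci, nj),
                                                j = max(ci, nj),
                                                type = "peptide"))
    }
  }
  sc <- sc[!duplicated(paste(sc$i, sc$j, sc$type)), , drop = FALSE]
  molecular_system(new_at, bonds, sc)
}
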