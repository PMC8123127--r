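#' Read a PDB file into an atom table
#'
#' Parses ATOM/HETATM records (via `bio3d::read.pdb`) into a flat atom
#' table with one row per atom.  Alternate locations are resolved by
#' keeping, for each (chain, residue, atom name), the location with
#' the highest occupancy, ties broken by alphabetical altloc id.
#' Waters are retained and can be excluded downstream via selection.
#'
#' @param path path to a PDB-format file.
#' @return A data frame of class `structure_model` with columns
#'   `chain`, `resno`, `insert`, `resid`, `elety` (atom name),
#'   `element`, `alt`, `occupancy`, `x`, `y`, `z`; the entry id (from
#'   the file name) is stored in attribute `entry`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom)) {
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  }
  # validate the fixed-width coordinate fields before delegating
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed coordinate record at line ", i, ": record too short",
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop("malformed coordinate record at line ", i,
           ": unparseable coordinates", call. = FALSE)
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  a <- pdb$atom
  element <- a$elesy
  missing_el <- is.na(element) | trimws(element) == ""
  element[missing_el] <- substr(gsub("[^A-Za-z].*", "", trimws(a$elety[missing_el])), 1, 1)
  model <- data.frame(
    chain = a$chain, resno = a$resno,
    insert = ifelse(is.na(a$insert), "", a$insert),
    resid = a$resid, elety = a$elety,
    element = toupper(trimws(element)),
    alt = ifelse(is.na(a$alt), "", a$alt),
    occupancy = ifelse(is.na(a$o), 1, a$o),
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(as.matrix(model[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path, call. = FALSE)
  }
  # altloc disambiguation: highest occupancy, ties alphabetical
  key <- paste(model$chain, model$resno, model$insert, model$resid,
               model$elety, sep = "|")
  ord <- order(key, -model$occupancy, model$alt)
  model <- model[ord, ]
  model <- model[!duplicated(paste(model$chain, model$resno, model$insert,
                                   model$resid, model$elety, sep = "|")), ]
  model <- model[order(model$chain, model$resno, model$insert), ]
  rownames(model) <- NULL
  attr(model, "entry") <- sub("\\.(pdb|ent)$", "", basename(path),
                              ignore.case = TRUE)
  class(model) <- c("structure_model", "data.frame")
  model
}

#' Write an atom table to PDB format
#'
#' Writes a `structure_model` as fixed-width ATOM (standard residues)
#' and HETATM (everything else) records, terminated by END.  The
#' output round-trips through [read_structure()].
#'
#' @param model a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  std <- model$resid %in% names(polar_templates())
  name4 <- ifelse(nchar(model$elety) < 4 & nchar(model$element) == 1,
                  sprintf(" %-3s", model$elety), sprintf("%-4s", model$elety))
  rec <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 ifelse(std, "ATOM", "HETATM"), seq_len(nrow(model)),
                 name4, substr(model$alt, 1, 1), model$resid, model$chain,
                 model$resno, substr(model$insert, 1, 1),
                 model$x, model$y, model$z, model$occupancy, 0,
                 model$element)
  writeLines(c(rec, "END"), path)
  invisible(path)
}

#' Select atoms with a chain:resno:atomname mini-grammar
#'
#' Subsets an atom table either by explicit arguments or by a compact
#' selector string `"chain:resno:atomname"` where each field may be
#' `*` (wildcard).  Examples: `"A:109:*"` (all atoms of residue 109 of
#' chain A), `"*:*:CA"` (all alpha carbons).
#'
#' @param model a `structure_model`.
#' @param spec optional selector string.
#' @param chain,resno,resid,elety,element optional explicit filters
#'   (vectors allowed).
#' @return The matching rows, still a `structure_model`.
#' @export
select_atoms <- function(model, spec = NULL, chain = NULL, resno = NULL,
                         resid = NULL, elety = NULL, element = NULL) {
  stopifnot(inherits(model, "structure_model"))
  keep <- rep(TRUE, nrow(model))
  if (!is.null(spec)) {
    parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
    if (length(parts) != 3L) {
      stop("selector must have the form chain:resno:atomname", call. = FALSE)
    }
    if (parts[1] != "*") keep <- keep & model$chain %in% parts[1]
    if (parts[2] != "*") keep <- keep & model$resno %in% as.integer(parts[2])
    if (parts[3] != "*") keep <- keep & model$elety %in% parts[3]
  }
  if (!is.null(chain)) keep <- keep & model$chain %in% chain
  if (!is.null(resno)) keep <- keep & model$resno %in% resno
  if (!is.null(resid)) keep <- keep & model$resid %in% resid
  if (!is.null(elety)) keep <- keep & model$elety %in% elety
  if (!is.null(element)) keep <- keep & model$element %in% element
  out <- model[keep, , drop = FALSE]
  class(out) <- class(model)
  attr(out, "entry") <- attr(model, "entry")
  out
}

coords_of <- function(x) {
  if (inherits(x, "structure_model") || is.data.frame(x)) {
    as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
    if (ncol(m) != 3L) stop("coordinates must be n x 3", call. = FALSE)
    m
  }
}

#' Minimum distance between two atom sets
#'
#' Minimum pairwise Euclidean distance between two non-empty atom sets
#' (atom tables or n x 3 coordinate matrices), together with the
#' realizing pair of row indices.
#'
#' @param set_A,set_B atom tables or coordinate matrices.
#' @return A list with `distance` (Angstrom) and `pair` (row indices
#'   `i` in A, `j` in B).
#' @export
min_distance <- function(set_A, set_B) {
  A <- coords_of(set_A); B <- coords_of(set_B)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop("both atom sets must be non-empty", call. = FALSE)
  }
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  idx <- arrayInd(which.min(d2), dim(d2))
  list(distance = sqrt(d2[idx]), pair = c(i = idx[1], j = idx[2]))
}

# polar (donor/acceptor) heavy atoms per standard residue template;
# backbone N is a donor and O an acceptor for all of them
polar_templates <- function() {
  list(
    ALA = character(), GLY = character(), VAL = character(),
    LEU = character(), ILE = character(), PRO = character(),
    PHE = character(), MET = character(),
    SER = "OG", THR = "OG1", CYS = character(), TYR = "OH",
    ASN = c("OD1", "ND2"), GLN = c("OE1", "NE2"),
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    HIS = c("ND1", "NE2"), LYS = "NZ",
    ARG = c("NE", "NH1", "NH2"), TRP = "NE1",
    HOH = "O"
  )
}

#' Hydrogen-bond inventory between a ligand and its environment
#'
#' Lists all polar heavy-atom pairs (N, O, F on the ligand side; the
#' residue-template polar atoms plus backbone N/O on the protein side)
#' within a distance cutoff.  With medium-resolution coordinates no
#' hydrogen positions or angle terms are available, so the criterion
#' is distance-only (default 3.5 Angstrom, configurable); the contact
#' count is monotone non-decreasing in the cutoff.
#'
#' @param model a `structure_model`.
#' @param ligand a `structure_model` subset (e.g. from
#'   [select_atoms()]) defining the ligand atoms.
#' @param cutoff donor-acceptor heavy-atom distance cutoff (Angstrom).
#' @param include_water include water oxygens as partners.
#' @return A `contact_report` data frame: one row per contact with the
#'   ligand atom, partner chain/residue/atom, distance and type.
#' @export
hbond_inventory <- function(model, ligand, cutoff = 3.5,
                            include_water = FALSE) {
  stopifnot(inherits(model, "structure_model"),
            inherits(ligand, "structure_model"))
  if (nrow(ligand) == 0L) stop("empty ligand selection", call. = FALSE)
  lig_polar <- ligand[ligand$element %in% c("N", "O", "F"), , drop = FALSE]
  templ <- polar_templates()
  lig_key <- paste(ligand$chain, ligand$resno, ligand$insert, ligand$resid)
  env <- model[!(paste(model$chain, model$resno, model$insert, model$resid)
                 %in% lig_key), , drop = FALSE]
  known <- env$resid %in% names(templ)
  if (any(!known)) {
    warning("skipping atoms of unknown residue template(s): ",
            paste(unique(env$resid[!known]), collapse = ", "))
    env <- env[known, , drop = FALSE]
  }
  if (!include_water) env <- env[env$resid != "HOH", , drop = FALSE]
  polar <- mapply(function(res, name) {
    name %in% c("N", "O") || name %in% templ[[res]]
  }, env$resid, env$elety)
  env <- env[polar, , drop = FALSE]
  contacts <- list()
  if (nrow(lig_polar) > 0L && nrow(env) > 0L) {
    A <- coords_of(lig_polar); B <- coords_of(env)
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
    d2[d2 < 0] <- 0
    hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (nrow(hits) > 0L) {
      contacts <- data.frame(
        ligand_atom = lig_polar$elety[hits[, 1]],
        ligand_resid = lig_polar$resid[hits[, 1]],
        chain = env$chain[hits[, 2]],
        resno = env$resno[hits[, 2]],
        resid = env$resid[hits[, 2]],
        atom = env$elety[hits[, 2]],
        distance = sqrt(d2[hits]),
        type = "hbond",
        stringsAsFactors = FALSE
      )
      contacts <- contacts[order(contacts$distance), ]
      rownames(contacts) <- NULL
    }
  }
  if (length(contacts) == 0L || nrow(contacts) == 0L) {
    contacts <- data.frame(ligand_atom = character(),
                           ligand_resid = character(), chain = character(),
                           resno = integer(), resid = character(),
                           atom = character(), distance = numeric(),
                           type = character(), stringsAsFactors = FALSE)
  }
  class(contacts) <- c("contact_report", "data.frame")
  contacts
}

# best-fit plane of a near-planar atom set: centroid + unit normal
ring_plane <- function(coords) {
  if (nrow(coords) < 3L) stop("a ring needs at least 3 atoms", call. = FALSE)
  centroid <- colMeans(coords)
  s <- svd(sweep(coords, 2, centroid))
  if (s$d[2] < 1e-8 * max(s$d[1], 1e-12)) {
    stop("ring atoms are collinear; no plane defined", call. = FALSE)
  }
  list(centroid = centroid, normal = s$v[, 3])
}

#' Ring-stacking geometry between two aromatic rings
#'
#' Centroid separation and interplanar angle (between best-fit plane
#' normals, folded to 0-90 degrees) of two near-planar atom sets, and
#' a stacking call using the common literature convention: centroid
#' distance at most 4.5 Angstrom and interplanar angle at most 30
#' degrees.
#'
#' @param ring_A,ring_B atom tables or coordinate matrices (at least
#'   3 non-collinear atoms each).
#' @param max_dist,max_angle stacking thresholds.
#' @return A list with `centroid_distance`, `angle_deg` and
#'   `stacking`.
#' @export
ring_stacking <- function(ring_A, ring_B, max_dist = 4.5, max_angle = 30) {
  pA <- ring_plane(coords_of(ring_A))
  pB <- ring_plane(coords_of(ring_B))
  d <- sqrt(sum((pA$centroid - pB$centroid)^2))
  cosang <- abs(sum(pA$normal * pB$normal))
  angle <- acos(min(max(cosang, 0), 1)) * 180 / pi
  list(centroid_distance = d, angle_deg = angle,
       stacking = d <= max_dist && angle <= max_angle)
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation and translation mapping paired point set A
#' onto B in the least-squares sense, via singular value decomposition
#' of the cross-covariance with the usual determinant correction, so a
#' reflection is never returned.  Collinear or coincident
#' configurations are rejected.
#'
#' @param set_A,set_B paired atom tables or n x 3 matrices, equal
#'   length, n >= 3.
#' @return A list with `rotation` (3 x 3, det +1), `translation`
#'   (length 3: `B - A %*% R`), `rmsd` after superposition, and
#'   `transform(x)` applying the motion to new coordinates.
#' @export
kabsch_superpose <- function(set_A, set_B) {
  A <- coords_of(set_A); B <- coords_of(set_B)
  if (nrow(A) != nrow(B)) {
    stop("paired sets must have equal length", call. = FALSE)
  }
  if (nrow(A) < 3L) stop("need at least 3 paired points", call. = FALSE)
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  if (min(svd(A0)$d[2], svd(B0)$d[2]) < 1e-8) {
    stop("degenerate (collinear or coincident) point configuration",
         call. = FALSE)
  }
  H <- t(A0) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  A_fit <- A0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((A_fit - B0)^2)))
  translation <- cB - as.vector(R %*% cA)
  list(rotation = R, translation = translation, rmsd = rmsd,
       transform = function(x) {
         sweep(coords_of(x) %*% t(R), 2, translation, "+")
       })
}

#' All-pairs C-alpha RMSD between chains of a structure
#'
#' Superposes every pair of chains on their shared C-alpha atoms
#' (matched by residue number) and reports the RMSD, with the number
#' of atoms actually paired.
#'
#' @param model a `structure_model`.
#' @param chains chains to compare (default: all chains that have
#'   C-alpha atoms).
#' @return Data frame with columns `chain_A`, `chain_B`, `n_atoms`,
#'   `rmsd`.
#' @export
chain_rmsd_matrix <- function(model, chains = NULL) {
  ca <- select_atoms(model, elety = "CA")
  ca <- ca[ca$resid != "CA", , drop = FALSE]  # guard against calcium ions
  if (is.null(chains)) chains <- unique(ca$chain)
  if (length(chains) < 2L) stop("need at least two chains", call. = FALSE)
  out <- list()
  for (i in seq_along(chains)) {
    for (j in seq_along(chains)) {
      if (j <= i) next
      a <- ca[ca$chain == chains[i], ]
      b <- ca[ca$chain == chains[j], ]
      shared <- intersect(a$resno, b$resno)
      a <- a[match(shared, a$resno), ]
      b <- b[match(shared, b$resno), ]
      fit <- kabsch_superpose(a, b)
      out[[length(out) + 1L]] <- data.frame(
        chain_A = chains[i], chain_B = chains[j],
        n_atoms = length(shared), rmsd = fit$rmsd,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Ligand pose RMSD between two structures in a common frame
#'
#' Superposes structure A onto structure B using paired frame atoms
#' (e.g. active-site C-alpha sets), applies the resulting rigid motion
#' to the ligand of A, and computes the RMSD over ligand atoms
#' corresponded by atom name - without any further fitting, so the
#' value reflects the pose difference within the common frame.
#'
#' @param ligand_A,ligand_B ligand atom tables.
#' @param frame_A,frame_B paired frame atom tables (equal length, in
#'   corresponding order).
#' @param name_map optional named character vector renaming ligand-A
#'   atom names to their ligand-B equivalents (e.g. a fluorine
#'   substituent matched to the parent carbon substituent).
#' @return RMSD in Angstrom over the corresponded ligand atoms.
#' @export
ligand_pose_rmsd <- function(ligand_A, ligand_B, frame_A, frame_B,
                             name_map = NULL) {
  fit <- kabsch_superpose(frame_A, frame_B)
  names_A <- ligand_A$elety
  if (!is.null(name_map)) {
    hit <- names_A %in% names(name_map)
    names_A[hit] <- name_map[names_A[hit]]
  }
  shared <- intersect(names_A, ligand_B$elety)
  if (length(shared) == 0L) {
    stop("no corresponded ligand atoms between the two structures",
         call. = FALSE)
  }
  A <- coords_of(ligand_A)[match(shared, names_A), , drop = FALSE]
  B <- coords_of(ligand_B)[match(shared, ligand_B$elety), , drop = FALSE]
  A_in_B <- fit$transform(A)
  sqrt(mean(rowSums((A_in_B - B)^2)))
}
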