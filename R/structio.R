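# Structure / trajectory / energy-table containers and their file formats.
#
# Conventions used throughout the package: coordinates in Angstrom, energies
# in kcal/mol, times in picoseconds, angles in degrees.  Frame indices are
# 0-based internally and 1-based in printed reports.

DNA_RESIDUES <- c("DA", "DT", "DG", "DC")
AA_RESIDUES <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")
WATER_RESIDUE <- "HOH"

#' Construct a molecular structure
#'
#' A structure is a topology plus one conformation: an ordered atom table
#' with PDB-style identifiers and Cartesian coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `serial` (unique positive integer),
#'   `name` (atom name, e.g. `"N1"`, `"OW"`), `element` (element symbol),
#'   `res_name` (residue code of up to 3 characters, e.g. `"DA"`, `"HOH"`),
#'   `res_seq` (integer residue number), `chain_id` (single character),
#'   `x`, `y`, `z` (Angstrom) and `record` (`"ATOM"` or `"HETATM"`).
#' @param title free-text title.
#' @return An object of class `pdb_structure`.
#' @export
pdb_structure <- function(atoms, title = "") {
  required <- c("serial", "name", "element", "res_name", "res_seq",
                "chain_id", "x", "y", "z", "record")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms[required], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (nrow(atoms) == 0L) stop("structure must contain at least one atom")
  if (anyDuplicated(atoms$serial))
    stop("atom serial numbers must be unique within a structure")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("atom coordinates must be finite")
  if (any(!nzchar(atoms$element)))
    stop("every atom needs a non-empty element symbol")
  key <- paste(atoms$chain_id, atoms$res_seq, atoms$name)
  if (anyDuplicated(key))
    stop("(chain_id, res_seq, name) must be unique; duplicated: ",
         key[anyDuplicated(key)])
  if (!all(atoms$record %in% c("ATOM", "HETATM")))
    stop("record must be ATOM or HETATM")
  structure(list(atoms = atoms, title = as.character(title)),
            class = "pdb_structure")
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  cat("<pdb_structure>", if (nzchar(x$title)) x$title else NULL, "\n")
  cat(sprintf("  %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain_id, a$res_seq))),
              paste(unique(a$chain_id), collapse = " ")))
  invisible(x)
}

#' Coordinates of a structure as a matrix
#'
#' @param s a `pdb_structure`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' Replace the coordinates of a structure
#' @param s a `pdb_structure`.
#' @param xyz n x 3 matrix matching the atom count.
#' @return the modified structure.
#' @export
set_coords <- function(s, xyz) {
  stopifnot(inherits(s, "pdb_structure"))
  xyz <- as.matrix(xyz)
  if (nrow(xyz) != nrow(s$atoms) || ncol(xyz) != 3L)
    stop("coordinate matrix must be ", nrow(s$atoms), " x 3")
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s
}

# --- atom selections ---------------------------------------------------------

residue_class <- function(res_name) {
  ifelse(res_name %in% DNA_RESIDUES, "dna",
         ifelse(res_name %in% AA_RESIDUES, "protein",
                ifelse(res_name == WATER_RESIDUE, "water", "other")))
}

#' Resolve an atom selection on a structure
#'
#' Selections are either a keyword (`"all"`, `"heavy"` = non-hydrogen,
#' `"protein"`, `"dna"`, `"water"`, or `"heavy"` combined with a class as in
#' `"heavy dna"`), a logical/integer index vector, or a predicate function
#' on the atom table.
#'
#' @param s a `pdb_structure`.
#' @param selection selection descriptor.
#' @return integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(s, selection = "all") {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  if (is.function(selection)) return(which(selection(a)))
  if (is.logical(selection)) {
    if (length(selection) != nrow(a)) stop("logical selection length mismatch")
    return(which(selection))
  }
  if (is.numeric(selection)) return(as.integer(selection))
  if (!is.character(selection) || length(selection) != 1L)
    stop("unsupported selection descriptor")
  keep <- rep(TRUE, nrow(a))
  for (tok in strsplit(trimws(selection), "[ &]+")[[1]]) {
    keep <- keep & switch(tok,
      all = TRUE,
      heavy = toupper(a$element) != "H",
      hydrogen = toupper(a$element) == "H",
      protein = residue_class(a$res_name) == "protein",
      dna = residue_class(a$res_name) == "dna",
      water = a$res_name == WATER_RESIDUE,
      stop("unknown selection keyword: '", tok, "'"))
  }
  which(keep)
}

# --- PDB reading / writing ---------------------------------------------------

parse_pdb_atoms <- function(lines, line_numbers) {
  n <- length(lines)
  num_field <- function(txt, lineno, what) {
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) & !is.na(txt))
    if (length(bad))
      stop(sprintf("unparseable %s field at line %d: '%s'",
                   what, lineno[bad[1]], txt[bad[1]]))
    v
  }
  lines <- sprintf("%-80s", lines)
  sub_ <- function(a, b) trimws(substr(lines, a, b))
  serial <- num_field(sub_(7, 11), line_numbers, "serial")
  name <- sub_(13, 16)
  res_name <- sub_(18, 20)
  chain_id <- sub_(22, 22)
  res_seq <- num_field(sub_(23, 26), line_numbers, "residue-number")
  x <- num_field(sub_(31, 38), line_numbers, "coordinate")
  y <- num_field(sub_(39, 46), line_numbers, "coordinate")
  z <- num_field(sub_(47, 54), line_numbers, "coordinate")
  element <- sub_(77, 78)
  # fall back to the first alphabetic character of the atom name
  no_el <- !nzchar(element)
  element[no_el] <- substr(gsub("[^A-Za-z].*$", "",
                                gsub("^[0-9']+", "", name[no_el])), 1, 1)
  element <- toupper(element)
  element[substr(name, 1, 1) %in% c("H") | grepl("^[0-9]*H", name)] <-
    ifelse(nzchar(element[substr(name, 1, 1) %in% c("H") |
                            grepl("^[0-9]*H", name)]),
           element[substr(name, 1, 1) %in% c("H") | grepl("^[0-9]*H", name)],
           "H")
  data.frame(serial = as.integer(serial), name = name, element = element,
             res_name = res_name, res_seq = as.integer(res_seq),
             chain_id = chain_id, x = x, y = y, z = z,
             record = trimws(substr(lines, 1, 6)),
             stringsAsFactors = FALSE)
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records (wwPDB v3.3 layout, coordinates
#' in columns 31-54).  If the file holds several MODEL blocks only the first
#' is kept, with a warning; use [read_trajectory()] for multi-model files.
#'
#' @param path path to a PDB file.
#' @return a [pdb_structure].
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines)) stop("empty PDB file: ", path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) > 1L) {
    warning(sprintf("file has %d MODEL blocks; keeping only the first",
                    length(model_starts)))
    ends <- which(trimws(rec) == "ENDMDL")
    lines <- lines[seq_len(ends[1])]
    rec <- rec[seq_len(ends[1])]
  }
  is_atom <- trimws(rec) %in% c("ATOM", "HETATM")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)
  title_lines <- lines[substr(lines, 1, 5) == "TITLE"]
  title <- if (length(title_lines)) trimws(substr(title_lines[1], 11, 80)) else ""
  pdb_structure(parse_pdb_atoms(lines[is_atom], which(is_atom)), title = title)
}

format_pdb_atom_line <- function(a) {
  name <- a$name
  # short names start in column 14 unless the element symbol is two letters
  name_fmt <- ifelse(nchar(name) >= 4L | nchar(a$element) == 2L,
                     sprintf("%-4s", name),
                     sprintf(" %-3s", name))
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, a$serial %% 100000L, name_fmt, a$res_name, a$chain_id,
          a$res_seq %% 10000L, a$x, a$y, a$z, 1.00, 0.00,
          toupper(a$element))
}

#' Write a structure to a PDB file
#'
#' @param s a [pdb_structure].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "pdb_structure"))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(s$title)) writeLines(sprintf("TITLE     %s", s$title), con)
  writeLines(structure_body_lines(s), con)
  writeLines("END", con)
  invisible(path)
}

structure_body_lines <- function(s) {
  a <- s$atoms
  out <- character(0)
  for (ch in unique(a$chain_id)) {
    blk <- a[a$chain_id == ch, , drop = FALSE]
    out <- c(out, format_pdb_atom_line(blk),
             if (any(blk$record == "ATOM")) "TER")
  }
  out
}

# --- trajectories ------------------------------------------------------------

#' Construct a trajectory
#'
#' Ordered conformations over a fixed topology.
#'
#' @param topology a [pdb_structure]; its coordinates are not themselves a
#'   frame unless included in `frames`.
#' @param frames list of n_atoms x 3 coordinate matrices (Angstrom).
#' @param dt_ps frame spacing, picoseconds (> 0).
#' @param run_id optional replicate identifier.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(topology, frames, dt_ps, run_id = NULL) {
  stopifnot(inherits(topology, "pdb_structure"))
  if (!length(frames)) stop("trajectory needs at least one frame")
  n <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    frames[[i]] <- as.matrix(frames[[i]])
    if (nrow(frames[[i]]) != n || ncol(frames[[i]]) != 3L)
      stop("frame ", i, " is not ", n, " x 3")
  }
  if (!is.numeric(dt_ps) || dt_ps <= 0) stop("dt_ps must be positive")
  structure(list(topology = topology, frames = frames,
                 dt_ps = as.numeric(dt_ps), run_id = run_id),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d frames x %d atoms, dt = %g ps%s\n",
              length(x$frames), nrow(x$topology$atoms), x$dt_ps,
              if (is.null(x$run_id)) "" else paste0(", run ", x$run_id)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a multi-model PDB trajectory
#'
#' Every MODEL block must contain the same atoms in topology order.  The
#' frame spacing is taken from a `REMARK   6 DT_PS <value>` header written
#' by [write_trajectory()], or from the `dt_ps` argument.
#'
#' @param path multi-model PDB path.
#' @param topology optional [pdb_structure]; defaults to the first model.
#' @param dt_ps frame spacing override, ps.
#' @return an [md_trajectory].
#' @export
read_trajectory <- function(path, topology = NULL, dt_ps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  if (!length(lines)) stop("empty trajectory file: ", path)
  rec <- trimws(substr(lines, 1, 6))
  dt_line <- grep("^REMARK +6 +DT_PS", lines, value = TRUE)
  if (is.null(dt_ps) && length(dt_line))
    dt_ps <- as.numeric(sub("^REMARK +6 +DT_PS +", "", dt_line[1]))
  dt_ps <- dt_ps %||% 1
  starts <- which(rec == "MODEL")
  ends <- which(rec == "ENDMDL")
  if (!length(starts)) { starts <- 0L; ends <- length(lines) + 1L }
  if (length(starts) != length(ends))
    stop("unbalanced MODEL/ENDMDL records in ", path)
  frames <- vector("list", length(starts))
  for (m in seq_along(starts)) {
    idx <- (starts[m] + 1L):(ends[m] - 1L)
    sel <- idx[rec[idx] %in% c("ATOM", "HETATM")]
    atoms <- parse_pdb_atoms(lines[sel], sel)
    if (m == 1L && is.null(topology))
      topology <- pdb_structure(atoms)
    if (nrow(atoms) != nrow(topology$atoms))
      stop(sprintf("model %d has %d atoms but the topology has %d",
                   m, nrow(atoms), nrow(topology$atoms)))
    frames[[m]] <- as.matrix(atoms[, c("x", "y", "z")])
  }
  md_trajectory(topology, frames, dt_ps)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an [md_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "md_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("REMARK   6 DT_PS %g", traj$dt_ps), con)
  s <- traj$topology
  for (m in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL %8d", m), con)
    writeLines(structure_body_lines(set_coords(s, traj$frames[[m]])), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# --- energy series -----------------------------------------------------------

#' Construct a ligand-surrounding interaction-energy series
#'
#' Per-sample electrostatic and van der Waals interaction energies between
#' the ligand selection and its surrounding, for one (variant, environment)
#' system.
#'
#' @param variant `"AT"` (wild-type pair) or `"GC"` (substituted pair).
#' @param environment `"Complex"` (protein-bound) or `"DNA"` (free DNA).
#' @param e_vdw,e_el equal-length numeric vectors, kcal/mol.
#' @param ligand_label free-text descriptor of the ligand atom selection.
#' @param sample_interval_ps spacing between samples, ps.
#' @return object of class `energy_series`.
#' @export
energy_series <- function(variant, environment, e_vdw, e_el,
                          ligand_label = "rSNP base pair",
                          sample_interval_ps = 0.02) {
  variant <- match.arg(variant, c("AT", "GC"))
  environment <- match.arg(environment, c("Complex", "DNA"))
  e_vdw <- as.numeric(e_vdw); e_el <- as.numeric(e_el)
  if (length(e_vdw) != length(e_el) || length(e_vdw) < 1L)
    stop("e_vdw and e_el must have equal length >= 1")
  if (!all(is.finite(e_vdw)) || !all(is.finite(e_el)))
    stop("energy values must be finite")
  structure(list(variant = variant, environment = environment,
                 ligand_label = ligand_label, e_vdw = e_vdw, e_el = e_el,
                 sample_interval_ps = as.numeric(sample_interval_ps)),
            class = "energy_series")
}

#' @export
print.energy_series <- function(x, ...) {
  cat(sprintf("<energy_series> %s / %s, %d samples every %g ps\n",
              x$variant, x$environment, length(x$e_vdw),
              x$sample_interval_ps))
  cat(sprintf("  <E_vdw> = %.3f, <E_el> = %.3f kcal/mol\n",
              mean(x$e_vdw), mean(x$e_el)))
  invisible(x)
}

#' Read an interaction-energy table
#'
#' Format: `# key=value` header lines carrying `variant`, `environment`,
#' `ligand_label` and `sample_interval_ps`, then a `sample,e_vdw,e_el` CSV
#' header and numeric rows.  `sample_interval_ps` defaults to 0.02 ps
#' (10 MD steps of 2 fs) when absent.
#'
#' @param path file path.
#' @return an [energy_series].
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  for (key in c("variant", "environment"))
    if (is.null(meta[[key]]))
      stop("energy table ", path, " lacks required metadata '# ", key, "='")
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) stop("energy table ", path, " has no data rows")
  header <- strsplit(lines[body_idx[1]], ",")[[1]]
  if (!identical(trimws(header), c("sample", "e_vdw", "e_el")))
    stop("energy table header must be 'sample,e_vdw,e_el'")
  rows <- strsplit(lines[body_idx[-1]], ",")
  parse_row <- function(r, lineno) {
    v <- suppressWarnings(as.numeric(r))
    if (length(v) != 3L || any(is.na(v)))
      stop(sprintf("non-numeric energy-table row at line %d", lineno))
    v
  }
  vals <- t(mapply(parse_row, rows, body_idx[-1]))
  energy_series(meta$variant, meta$environment,
                e_vdw = vals[, 2], e_el = vals[, 3],
                ligand_label = meta$ligand_label %||% "",
                sample_interval_ps =
                  as.numeric(meta$sample_interval_ps %||% 0.02))
}

#' Write an interaction-energy table
#'
#' @param es an [energy_series].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_energy_table <- function(es, path) {
  stopifnot(inherits(es, "energy_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# variant=%s", es$variant),
               sprintf("# environment=%s", es$environment),
               sprintf("# ligand_label=%s", es$ligand_label),
               sprintf("# sample_interval_ps=%.17g", es$sample_interval_ps),
               "sample,e_vdw,e_el",
               sprintf("%d,%.17g,%.17g", seq_along(es$e_vdw),
                       es$e_vdw, es$e_el)), con)
  invisible(path)
}
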