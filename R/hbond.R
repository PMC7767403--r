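# Strictly geometric hydrogen-bond and water-bridge detection.
#
# A hydrogen bond exists when the donor-acceptor distance is below d_max
# (default 3.0 A) and the angle at the donor between D->H and D->A is below
# theta_max (default 20 degrees); both inequalities are strict, boundary
# values are excluded.

#' Hydrogen-bond geometric criteria
#'
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param theta_max hydrogen-donor-acceptor angle cutoff, degrees; small
#'   angles mean a near-linear D-H...A arrangement.
#' @return object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.0, theta_max = 20.0) {
  if (!is.numeric(d_max) || d_max <= 0) stop("d_max must be > 0")
  if (!is.numeric(theta_max) || theta_max <= 0 || theta_max >= 90)
    stop("theta_max must be in (0, 90) degrees")
  structure(list(d_max = as.numeric(d_max),
                 theta_max = as.numeric(theta_max)),
            class = "hbond_criteria")
}

# Fixed donor/acceptor chemistry dictionary: Watson-Crick base faces and
# base-ring edges, nucleotide backbone oxygens, protein backbone N-H / C=O,
# H-bonding side chains, and water.  Donor entries are heavy atoms that may
# carry polar hydrogens; which hydrogens they actually carry is resolved
# geometrically on the structure.
da_dictionary <- function() {
  bb_nuc <- c("O1P", "O2P", "O3'", "O4'", "O5'")
  aa <- function(donors = character(0), acceptors = character(0))
    list(donors = c("N", donors), acceptors = c("O", "OXT", acceptors))
  d <- list(
    DA = list(donors = "N6", acceptors = c("N1", "N3", "N7", bb_nuc)),
    DT = list(donors = "N3", acceptors = c("O2", "O4", bb_nuc)),
    DG = list(donors = c("N1", "N2"), acceptors = c("O6", "N3", "N7", bb_nuc)),
    DC = list(donors = "N4", acceptors = c("N3", "O2", bb_nuc)),
    HOH = list(donors = "OW", acceptors = "OW"),
    SER = aa("OG", "OG"), THR = aa("OG1", "OG1"), TYR = aa("OH", "OH"),
    CYS = aa("SG"), ASN = aa("ND2", "OD1"), GLN = aa("NE2", "OE1"),
    LYS = aa("NZ"), ARG = aa(c("NE", "NH1", "NH2")),
    HIS = aa(c("ND1", "NE2"), c("ND1", "NE2")), TRP = aa("NE1"),
    ASP = aa(acceptors = c("OD1", "OD2")),
    GLU = aa(acceptors = c("OE1", "OE2")))
  for (res in setdiff(AA_RESIDUES, names(d))) d[[res]] <- aa()
  d
}

#' Assign hydrogen-bond donors and acceptors
#'
#' Applies the package's fixed chemistry dictionary (standard nucleotides,
#' the 20 amino acids, water) to a structure with explicit polar hydrogens.
#' Every hydrogen is attached to its nearest non-hydrogen atom, which must
#' lie within 1.2 Angstrom; a donor is a dictionary heavy atom carrying at
#' least one attached hydrogen.
#'
#' @param s a [pdb_structure].
#' @return object of class `da_table`: `donors` (data.frame with atom
#'   index `donor` and a list-column `hydrogens` of attached hydrogen
#'   indices) and `acceptors` (integer atom indices).
#' @export
assign_donors_acceptors <- function(s) {
  stopifnot(inherits(s, "pdb_structure"))
  a <- s$atoms
  xyz <- coords(s)
  dict <- da_dictionary()
  is_h <- toupper(a$element) == "H"
  heavy_idx <- which(!is_h)
  h_parent <- integer(0)
  if (any(is_h)) {
    if (!length(heavy_idx)) stop("structure has hydrogens but no heavy atoms")
    h_parent <- vapply(which(is_h), function(i) {
      d2 <- colSums((t(xyz[heavy_idx, , drop = FALSE]) - xyz[i, ])^2)
      j <- which.min(d2)
      if (d2[j] > 1.2^2)
        stop(sprintf(
          "hydrogen %s %s%d:%s has no heavy atom within 1.2 A",
          a$chain_id[i], a$res_name[i], a$res_seq[i], a$name[i]))
      heavy_idx[j]
    }, integer(1))
  } else {
    warning("structure contains no hydrogens; no donors can be assigned")
  }
  entry <- dict[a$res_name]
  donor_ok <- mapply(function(e, nm) !is.null(e) && nm %in% e$donors,
                     entry, a$name)
  acceptor_ok <- mapply(function(e, nm) !is.null(e) && nm %in% e$acceptors,
                        entry, a$name)
  hyd_by_parent <- split(which(is_h), h_parent)
  donors_idx <- intersect(which(donor_ok), as.integer(names(hyd_by_parent)))
  donors <- data.frame(donor = donors_idx)
  donors$hydrogens <- unname(hyd_by_parent[as.character(donors_idx)])
  structure(list(donors = donors, acceptors = which(acceptor_ok)),
            class = "da_table")
}

#' @export
print.da_table <- function(x, ...) {
  cat(sprintf("<da_table> %d donors, %d acceptors\n",
              nrow(x$donors), length(x$acceptors)))
  invisible(x)
}

#' Detect hydrogen bonds in one conformation
#'
#' Emits one event per (donor, hydrogen, acceptor) triple satisfying the
#' criteria.  The donor heavy atom and the acceptor must be distinct and
#' not covalently bonded (heavy-heavy distance > 1.8 A).
#'
#' @param s a [pdb_structure] (supplies topology and, by default,
#'   coordinates).
#' @param criteria an [hbond_criteria].
#' @param da optional precomputed [assign_donors_acceptors()] table.
#' @param xyz optional n x 3 frame coordinates overriding the structure's.
#' @param frame frame index stored with the events (0-based).
#' @return data.frame of events: `donor`, `hydrogen`, `acceptor` (atom
#'   indices), `distance` (A), `angle` (degrees), `frame`, plus readable
#'   `donor_label` / `acceptor_label`.
#' @export
detect_hbonds <- function(s, criteria = hbond_criteria(), da = NULL,
                          xyz = NULL, frame = 0L) {
  stopifnot(inherits(s, "pdb_structure"))
  da <- da %||% assign_donors_acceptors(s)
  xyz <- if (is.null(xyz)) coords(s) else as.matrix(xyz)
  acc <- da$acceptors
  out <- list()
  lab <- function(i) sprintf("%s:%s%d:%s", s$atoms$chain_id[i],
                             s$atoms$res_name[i], s$atoms$res_seq[i],
                             s$atoms$name[i])
  if (!nrow(da$donors) || !length(acc)) return(empty_hbond_events())
  axyz <- xyz[acc, , drop = FALSE]
  for (k in seq_len(nrow(da$donors))) {
    d_i <- da$donors$donor[k]
    dpos <- xyz[d_i, ]
    dd <- sqrt(colSums((t(axyz) - dpos)^2))
    cand <- which(dd < criteria$d_max & dd > 1.8 & acc != d_i)
    if (!length(cand)) next
    for (h_i in da$donors$hydrogens[[k]]) {
      dh <- xyz[h_i, ] - dpos
      for (ci in cand) {
        a_i <- acc[ci]
        dav <- axyz[ci, ] - dpos
        cosang <- sum(dh * dav) / (vec_norm(dh) * vec_norm(dav))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang < criteria$theta_max) {
          out[[length(out) + 1L]] <- data.frame(
            donor = d_i, hydrogen = h_i, acceptor = a_i,
            distance = dd[ci], angle = ang, frame = as.integer(frame),
            donor_label = lab(d_i), acceptor_label = lab(a_i),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty_hbond_events())
  do.call(rbind, out)
}

empty_hbond_events <- function() {
  data.frame(donor = integer(0), hydrogen = integer(0),
             acceptor = integer(0), distance = numeric(0),
             angle = numeric(0), frame = integer(0),
             donor_label = character(0), acceptor_label = character(0),
             stringsAsFactors = FALSE)
}

#' Detect water-mediated protein-DNA bridges in one conformation
#'
#' A bridge is a water molecule whose oxygen lies within `radius` of
#' `site_center` and that simultaneously hydrogen-bonds (in either
#' donor/acceptor direction) to at least one protein atom and at least one
#' DNA atom.  One bridge is reported per qualifying water per frame.
#'
#' @param s a [pdb_structure] containing protein, DNA and water residues.
#' @param site_center 3-vector, Angstrom (e.g. the substitution-site
#'   base-pair centroid from [pair_centroid()]).
#' @param radius search radius around `site_center`, Angstrom.
#' @param criteria an [hbond_criteria].
#' @param da,xyz,frame as in [detect_hbonds()].
#' @return data.frame with one row per bridge: water identifiers, the
#'   protein-side and DNA-side partner atom labels, and `frame`.
#' @export
detect_water_bridges <- function(s, site_center, radius = 10.0,
                                 criteria = hbond_criteria(), da = NULL,
                                 xyz = NULL, frame = 0L) {
  stopifnot(inherits(s, "pdb_structure"))
  xyz <- if (is.null(xyz)) coords(s) else as.matrix(xyz)
  a <- s$atoms
  cls <- residue_class(a$res_name)
  empty <- data.frame(water_chain = character(0), water_res = integer(0),
                      protein_partner = character(0),
                      dna_partner = character(0), frame = integer(0),
                      stringsAsFactors = FALSE)
  ow <- which(a$res_name == WATER_RESIDUE & a$name == "OW")
  if (!length(ow)) {
    warning("structure contains no water; no bridges can exist")
    return(empty)
  }
  events <- detect_hbonds(s, criteria, da = da, xyz = xyz, frame = frame)
  if (!nrow(events)) return(empty)
  side <- function(idx) cls[idx]
  bridges <- list()
  for (o in ow) {
    if (vec_norm(xyz[o, ] - site_center) >= radius) next
    wres <- a$res_seq[o]; wch <- a$chain_id[o]
    in_water <- a$chain_id[events$donor] == wch &
      a$res_seq[events$donor] == wres & a$res_name[events$donor] == WATER_RESIDUE
    in_water_acc <- a$chain_id[events$acceptor] == wch &
      a$res_seq[events$acceptor] == wres &
      a$res_name[events$acceptor] == WATER_RESIDUE
    partner <- ifelse(in_water, events$acceptor,
                      ifelse(in_water_acc, events$donor, NA_integer_))
    wev <- which(!is.na(partner))
    if (!length(wev)) next
    pcls <- side(partner[wev])
    prot <- wev[pcls == "protein"]; dna <- wev[pcls == "dna"]
    if (length(prot) && length(dna)) {
      plab <- sprintf("%s:%s%d:%s", a$chain_id[partner[prot[1]]],
                      a$res_name[partner[prot[1]]],
                      a$res_seq[partner[prot[1]]], a$name[partner[prot[1]]])
      dlab <- sprintf("%s:%s%d:%s", a$chain_id[partner[dna[1]]],
                      a$res_name[partner[dna[1]]],
                      a$res_seq[partner[dna[1]]], a$name[partner[dna[1]]])
      bridges[[length(bridges) + 1L]] <- data.frame(
        water_chain = wch, water_res = wres, protein_partner = plab,
        dna_partner = dlab, frame = as.integer(frame),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(bridges)) return(empty)
  do.call(rbind, bridges)
}

#' Detect hydrogen bonds across a trajectory
#'
#' Donor/acceptor assignment is done once on the topology; the per-frame
#' geometry then decides which bonds exist.
#'
#' @param traj an [md_trajectory].
#' @param criteria an [hbond_criteria].
#' @return list of per-frame event data.frames (see [detect_hbonds()]).
#' @export
hbond_trajectory <- function(traj, criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  da <- assign_donors_acceptors(traj$topology)
  lapply(seq_along(traj$frames), function(m)
    detect_hbonds(traj$topology, criteria, da = da, xyz = traj$frames[[m]],
                  frame = m - 1L))
}

#' Occupancy and lifetime statistics of hydrogen bonds
#'
#' Bonds are keyed by (donor heavy atom, acceptor), ignoring which hydrogen
#' satisfied the criteria, so e.g. rotating water hydrogens do not fragment
#' one bond into several.  A bond's events are its maximal runs of
#' consecutive frames of presence; each run's duration is its length times
#' `dt_ps`.
#'
#' @param events_by_frame list of per-frame event data.frames, one entry
#'   per frame ([hbond_trajectory()] output).
#' @param n_frames total number of frames (>= 1); defaults to
#'   `length(events_by_frame)`.
#' @param dt_ps frame spacing, ps.
#' @return object of class `hbond_summary`: `summary` data.frame (one row
#'   per bond key: `donor_label`, `acceptor_label`, `occupancy`,
#'   `mean_duration_ps`, `n_events`) and `counts`, the per-frame number of
#'   distinct bonds present.
#' @export
hbond_statistics <- function(events_by_frame, n_frames = NULL, dt_ps = 1) {
  n_frames <- n_frames %||% length(events_by_frame)
  if (n_frames < 1L) stop("n_frames must be >= 1")
  counts <- integer(n_frames)
  present <- list()  # key -> logical frame vector
  labels <- list()
  for (m in seq_along(events_by_frame)) {
    ev <- events_by_frame[[m]]
    if (!nrow(ev)) next
    keys <- unique(paste(ev$donor_label, ev$acceptor_label, sep = " -> "))
    counts[m] <- length(keys)
    for (k in keys) {
      if (is.null(present[[k]])) {
        present[[k]] <- logical(n_frames)
        row <- ev[match(k, paste(ev$donor_label, ev$acceptor_label,
                                 sep = " -> ")), ]
        labels[[k]] <- c(row$donor_label, row$acceptor_label)
      }
      present[[k]][m] <- TRUE
    }
  }
  if (!length(present)) {
    summ <- data.frame(donor_label = character(0),
                       acceptor_label = character(0), occupancy = numeric(0),
                       mean_duration_ps = numeric(0), n_events = integer(0),
                       stringsAsFactors = FALSE)
  } else {
    summ <- do.call(rbind, lapply(names(present), function(k) {
      p <- present[[k]]
      r <- rle(p)
      runs <- r$lengths[r$values]
      data.frame(donor_label = labels[[k]][1],
                 acceptor_label = labels[[k]][2],
                 occupancy = sum(p) / n_frames,
                 mean_duration_ps = mean(runs) * dt_ps,
                 n_events = length(runs), stringsAsFactors = FALSE)
    }))
    summ <- summ[order(-summ$occupancy), ]
    rownames(summ) <- NULL
  }
  structure(list(summary = summ, counts = counts, n_frames = n_frames,
                 dt_ps = dt_ps),
            class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("<hbond_summary> %d bond keys over %d frames (dt %g ps)\n",
              nrow(x$summary), x$n_frames, x$dt_ps))
  cat(sprintf("  mean bonds per frame: %.2f\n", mean(x$counts)))
  if (nrow(x$summary)) print(utils::head(x$summary, 10))
  invisible(x)
}
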