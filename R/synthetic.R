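# Synthetic inputs: idealized B-DNA duplexes, base-pair substitution, toy
# protein-DNA complexes with a bridging water, noise trajectories with
# controllable rigidity, and AR(1) interaction-energy series for the
# four-system thermodynamic cycle.
#
# Base heavy-atom templates are expressed in the standard base-pair
# reference frame (long pair axis along y, major groove towards +x, base
# plane z = 0); the complementary base is obtained by the 180-degree flip
# about x and then rigidly snapped so that every Watson-Crick donor-
# acceptor distance is exactly 2.90 A.  Polar hydrogens are placed on the
# donor -> acceptor line (1.01 A), so each G:C pair carries 3 and each A:T
# pair 2 hydrogen bonds under the default criteria by construction.

BDNA_RISE <- 3.38    # A per step
BDNA_TWIST <- 36.0   # degrees per step
WC_TARGET <- 2.90    # snapped donor-acceptor distance, A
NH_BOND <- 1.01      # donor-hydrogen distance, A

base_template <- function(base) {
  tpl <- switch(base,
    A = list(
      N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897), N7 = c(0.877, 3.902),
      C5 = c(0.071, 2.771), C6 = c(0.369, 1.398), N6 = c(1.611, 0.909),
      N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023), N3 = c(-2.320, 2.290),
      C4 = c(-1.267, 3.124), `C1'` = c(-2.479, 5.346)),
    G = list(
      N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962), N7 = c(0.870, 3.969),
      C5 = c(0.071, 2.833), C6 = c(0.424, 1.460), O6 = c(1.554, 0.955),
      N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087), N2 = c(-2.949, 0.139),
      N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177), `C1'` = c(-2.477, 5.399)),
    C = list(
      N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158), O2 = c(-2.628, 2.709),
      N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868), N4 = c(1.875, 2.027),
      C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068), `C1'` = c(-2.477, 5.402)),
    T = list(
      N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.135), O2 = c(-2.562, 2.608),
      N3 = c(-0.298, 2.407), C4 = c(0.994, 2.897), O4 = c(1.944, 2.119),
      C5 = c(1.106, 4.338), C7 = c(2.466, 4.961), C6 = c(-0.024, 5.057),
      `C1'` = c(-2.481, 5.354)),
    stop("invalid base: '", base, "' (must be one of A, C, G, T)"))
  m <- do.call(rbind, tpl)
  cbind(m, 0)  # planar, z = 0
}

COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G")

# Watson-Crick contacts per pair type, as (donor strand, donor atom,
# acceptor strand, acceptor atom); strand 1 carries the first letter.
wc_contacts <- function(b1) {
  switch(b1,
    A = list(c(1, "N6", 2, "O4"), c(2, "N3", 1, "N1")),
    T = list(c(2, "N6", 1, "O4"), c(1, "N3", 2, "N1")),
    G = list(c(1, "N1", 2, "N3"), c(1, "N2", 2, "O2"), c(2, "N4", 1, "O6")),
    C = list(c(2, "N1", 1, "N3"), c(2, "N2", 1, "O2"), c(1, "N4", 2, "O6")))
}

# The hydrogen name carried by each Watson-Crick donor, and the name of the
# second amino hydrogen where the donor is an -NH2 group.
donor_hydrogens <- c(N6 = "H61", N1 = "H1", N2 = "H21", N4 = "H41",
                     N3 = "H3")
second_amino_h <- c(H61 = "H62", H21 = "H22", H41 = "H42")
# ring atom the amino nitrogen is bonded to (used to orient the second H)
amino_ring_neighbor <- c(N6 = "C6", N2 = "C2", N4 = "C4")

# Build one base pair in the local pair frame.  Returns a list of two
# "residues": matrices of named atom rows (heavy + polar H), element
# vector alongside.
build_pair_template <- function(b1) {
  b2 <- COMPLEMENT[[b1]]
  m1 <- base_template(b1)
  m2 <- base_template(b2)
  m2 <- m2 %*% diag(c(1, -1, -1))   # flip about x: antiparallel partner
  contacts <- wc_contacts(b1)
  strands <- list(m1, m2)
  # rigid translation snap of strand 2 so every WC heavy-atom distance
  # equals WC_TARGET (contacts are near-parallel, so this converges fast)
  for (it in 1:20) {
    shift <- c(0, 0, 0)
    for (ct in contacts) {
      d_at <- strands[[as.integer(ct[1])]][ct[2], ]
      a_at <- strands[[as.integer(ct[3])]][ct[4], ]
      v <- a_at - d_at
      if (ct[1] == "2" || ct[3] == "2") {
        # move strand 2 along the contact line towards the 2.90 A target
        sgn <- if (ct[1] == "2") -1 else 1   # direction acting on strand 2
        shift <- shift + sgn * (vec_norm(v) - WC_TARGET) * unit(v) /
          length(contacts)
      }
    }
    strands[[2]] <- sweep(strands[[2]], 2, shift)
    if (vec_norm(shift) < 1e-9) break
  }
  # place hydrogens
  hydro <- list(`1` = NULL, `2` = NULL)
  for (ct in contacts) {
    ds <- ct[1]; d_name <- ct[2]; as_ <- ct[3]; a_name <- ct[4]
    d_at <- strands[[as.integer(ds)]][d_name, ]
    a_at <- strands[[as.integer(as_)]][a_name, ]
    h1name <- donor_hydrogens[[d_name]]
    dir <- unit(a_at - d_at)
    hs <- rbind(d_at + NH_BOND * dir)
    rownames(hs) <- h1name
    if (h1name %in% names(second_amino_h)) {
      # second amino hydrogen: rotate the bonding H direction by +/-120
      # degrees in the base plane, picking the side away from the ring
      nb <- strands[[as.integer(ds)]][amino_ring_neighbor[[d_name]], ]
      cands <- lapply(c(120, -120), function(a)
        d_at + NH_BOND * as.numeric(rot_z(a) %*% dir))
      dist_nb <- vapply(cands, function(p) vec_norm(p - nb), numeric(1))
      h2 <- cands[[which.max(dist_nb)]]
      hs <- rbind(hs, h2)
      rownames(hs)[2] <- second_amino_h[[h1name]]
    }
    hydro[[ds]] <- rbind(hydro[[ds]], hs)
  }
  res <- list()
  for (k in 1:2) {
    m <- rbind(strands[[k]], hydro[[as.character(k)]])
    el <- ifelse(grepl("^H", rownames(m)), "H",
                 substr(rownames(m), 1, 1))
    res[[k]] <- list(base = if (k == 1) b1 else b2, xyz = m, element = el)
  }
  res
}

pair_transform <- function(index) {
  list(R = rot_z((index - 1) * BDNA_TWIST),
       t = c(0, 0, (index - 1) * BDNA_RISE))
}

residue_atom_rows <- function(res, chain, res_seq) {
  data.frame(serial = NA_integer_, name = rownames(res$xyz),
             element = res$element,
             res_name = paste0("D", res$base), res_seq = res_seq,
             chain_id = chain, x = res$xyz[, 1], y = res$xyz[, 2],
             z = res$xyz[, 3], record = "ATOM", stringsAsFactors = FALSE)
}

#' Build an idealized B-form DNA duplex
#'
#' Generates a right-handed double helix (rise 3.38 A, twist 36 degrees
#' per step) from a sequence over A/C/G/T, auto-generating the
#' complementary strand.  Residues carry base heavy atoms, the C1' anchor
#' and explicit polar hydrogens positioned so every G:C pair satisfies 3
#' and every A:T pair 2 hydrogen bonds under the default
#' [hbond_criteria()].  Chain A holds the given sequence (residues
#' numbered 1..n, 5'->3'), chain B the complement (residue i paired with
#' chain A residue i).
#'
#' @param sequence string over A/C/G/T, length >= 1.
#' @return a [pdb_structure] with attribute `"sequence"`.
#' @export
build_duplex <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty string")
  bases <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(bases, names(COMPLEMENT))
  if (length(bad))
    stop("invalid base: '", bad[1], "' (must be one of A, C, G, T)")
  rows_a <- list(); rows_b <- list()
  for (i in seq_along(bases)) {
    pt <- build_pair_template(bases[i])
    tf <- pair_transform(i)
    for (k in 1:2) {
      pt[[k]]$xyz <- sweep(pt[[k]]$xyz %*% t(tf$R), 2, -tf$t)
    }
    rows_a[[i]] <- residue_atom_rows(pt[[1]], "A", i)
    rows_b[[i]] <- residue_atom_rows(pt[[2]], "B", i)
  }
  atoms <- do.call(rbind, c(rows_a, rows_b))
  atoms$serial <- seq_len(nrow(atoms))
  s <- pdb_structure(atoms, title = sprintf("idealized B-DNA duplex %s",
                                            paste(bases, collapse = "")))
  attr(s, "sequence") <- paste(bases, collapse = "")
  s
}

duplex_sequence <- function(duplex) {
  seq_attr <- attr(duplex, "sequence")
  if (!is.null(seq_attr)) return(strsplit(seq_attr, "")[[1]])
  a <- duplex$atoms
  blk <- a[a$chain_id == "A", ]
  sub("^D", "", blk$res_name[match(sort(unique(blk$res_seq)), blk$res_seq)])
}

#' Substitute one base pair of a duplex
#'
#' Replaces both strands' residues at a pair position with the idealized
#' template of the new pair, fitted to the same local helical frame; all
#' other atoms keep their coordinates (serial numbers are refreshed).
#'
#' @param duplex a duplex from [build_duplex()].
#' @param position 1-based pair index.
#' @param new_pair `"AT"`, `"GC"`, `"TA"` or `"CG"`; the first letter goes
#'   to chain A.
#' @return the mutated [pdb_structure].
#' @export
mutate_pair <- function(duplex, position, new_pair = c("GC", "AT", "TA", "CG")) {
  stopifnot(inherits(duplex, "pdb_structure"))
  new_pair <- match.arg(new_pair)
  bases <- duplex_sequence(duplex)
  if (position < 1L || position > length(bases))
    stop("pair position ", position, " out of range 1..", length(bases))
  b1 <- substr(new_pair, 1, 1)
  if (COMPLEMENT[[b1]] != substr(new_pair, 2, 2))
    stop("'", new_pair, "' is not a Watson-Crick pair")
  pt <- build_pair_template(b1)
  tf <- pair_transform(position)
  for (k in 1:2) pt[[k]]$xyz <- sweep(pt[[k]]$xyz %*% t(tf$R), 2, -tf$t)
  a <- duplex$atoms
  splice <- function(tab, chain, res) {
    keep <- !(tab$chain_id == chain & tab$res_seq == res &
                tab$res_name %in% DNA_RESIDUES)
    at_res <- which(!keep)
    newrows <- residue_atom_rows(pt[[if (chain == "A") 1 else 2]], chain, res)
    # insert at the old residue's location to keep atom order stable
    pos <- if (length(at_res)) min(at_res) else nrow(tab) + 1L
    rbind(tab[seq_len(pos - 1L), ][keep[seq_len(pos - 1L)], , drop = FALSE],
          newrows,
          tab[seq(pos, length.out = nrow(tab) - pos + 1L), , drop = FALSE][
            keep[seq(pos, length.out = nrow(tab) - pos + 1L)], , drop = FALSE])
  }
  a <- splice(a, "A", position)
  a <- splice(a, "B", position)
  a$serial <- seq_len(nrow(a))
  bases[position] <- b1
  s <- pdb_structure(a, title = sprintf("idealized B-DNA duplex %s",
                                        paste(bases, collapse = "")))
  attr(s, "sequence") <- paste(bases, collapse = "")
  s
}

#' Centroid of a base pair's heavy atoms
#'
#' @param duplex a [pdb_structure] containing DNA chains A/B.
#' @param position 1-based pair index.
#' @return 3-vector, Angstrom.
#' @export
pair_centroid <- function(duplex, position) {
  a <- duplex$atoms
  sel <- a$chain_id %in% c("A", "B") & a$res_seq == position &
    a$res_name %in% DNA_RESIDUES & toupper(a$element) != "H"
  if (!any(sel)) stop("no base pair at position ", position)
  colMeans(as.matrix(a[sel, c("x", "y", "z")]))
}

#' Attach a minimal protein chain to a duplex
#'
#' Adds a two-residue peptide (SER-ASN, chain P) positioned in the major
#' groove of the given pair so that the serine hydroxyl donates a hydrogen
#' bond to the N7 of the site purine — guaranteeing at least one direct
#' protein-DNA contact — with the serine backbone carbonyl oriented to
#' admit a bridging water ([place_bridging_water()]).  DNA atoms are left
#' untouched.
#'
#' @param duplex a duplex from [build_duplex()] / [mutate_pair()].
#' @param site 1-based pair index of the contact site.
#' @return a [pdb_structure] with chains A, B and P.
#' @export
build_toy_complex <- function(duplex, site) {
  stopifnot(inherits(duplex, "pdb_structure"))
  a <- duplex$atoms
  pur <- which(a$res_seq == site & a$res_name %in% c("DA", "DG") &
                 a$name == "N7")
  if (!length(pur))
    stop("no purine N7 found at pair ", site,
         " (site must hold an A:T or G:C pair)")
  n7 <- as.numeric(a[pur[1], c("x", "y", "z")])
  cen <- pair_centroid(duplex, site)
  u <- unit(c((n7 - cen)[1:2], 0))       # in-plane outward direction
  ez <- c(0, 0, 1)
  d1 <- unit(0.8 * u + 0.6 * ez)
  og <- n7 + 2.85 * d1
  hg <- og - NH_BOND * d1                 # points back at N7: angle 0
  cb <- og + 1.45 * unit(u + ez)
  ca <- cb + 1.53 * unit(u + 0.3 * ez)
  nv <- as.numeric(rot_z(90) %*% u)
  n_at <- ca + 1.46 * unit(nv)
  h_at <- n_at + NH_BOND * unit(nv)
  o_target <- n7 + 2.0 * u - 3.9 * ez
  c_at <- ca + 1.53 * unit(o_target - ca)
  o_at <- c_at + 1.24 * unit(o_target - c_at)
  ser <- rbind(N = n_at, H = h_at, CA = ca, C = c_at, O = o_at, CB = cb,
               OG = og, HG = hg)
  shift <- 4.0 * u
  cb2 <- cb + shift; ca2 <- ca + shift
  cg2 <- cb2 + 1.52 * u
  od1 <- cg2 + 1.23 * as.numeric(rot_z(60) %*% u)
  nd2 <- cg2 + 1.33 * as.numeric(rot_z(-60) %*% u)
  hd21 <- nd2 + NH_BOND * u
  hd22 <- nd2 + NH_BOND * as.numeric(rot_z(-120) %*% u)
  asn <- rbind(N = n_at + shift, H = h_at + shift, CA = ca2,
               C = c_at + shift, O = o_at + shift, CB = cb2, CG = cg2,
               OD1 = od1, ND2 = nd2, HD21 = hd21, HD22 = hd22)
  mk <- function(m, res_name, res_seq) {
    data.frame(serial = NA_integer_, name = rownames(m),
               element = ifelse(grepl("^H", rownames(m)), "H",
                                substr(rownames(m), 1, 1)),
               res_name = res_name, res_seq = res_seq, chain_id = "P",
               x = m[, 1], y = m[, 2], z = m[, 3], record = "ATOM",
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(a, mk(ser, "SER", 1L), mk(asn, "ASN", 2L))
  atoms$serial <- seq_len(nrow(atoms))
  s <- pdb_structure(atoms, title = paste(duplex$title, "+ toy TF peptide"))
  attr(s, "sequence") <- attr(duplex, "sequence")
  attr(s, "site") <- site
  s
}

#' Place a water bridging the protein and the DNA
#'
#' Adds one HOH molecule (chain W; atoms OW/HW1/HW2) whose oxygen donates
#' one hydrogen to a DNA acceptor of the site pair (the purine N7) and one
#' to a nearby protein acceptor, forming exactly one water bridge within
#' 10 A of the site centroid.
#'
#' @param complex a structure from [build_toy_complex()].
#' @param site 1-based pair index.
#' @return a [pdb_structure] including the bridging water.
#' @export
place_bridging_water <- function(complex, site) {
  stopifnot(inherits(complex, "pdb_structure"))
  a <- complex$atoms
  if (!any(residue_class(a$res_name) == "protein"))
    stop("complex has no protein chain; build it with build_toy_complex()")
  pur <- which(a$res_seq == site & a$res_name %in% c("DA", "DG") &
                 a$name == "N7")
  if (!length(pur)) stop("no purine N7 at pair ", site)
  a_d <- as.numeric(a[pur[1], c("x", "y", "z")])
  prot_o <- which(a$chain_id == "P" & a$name == "O")
  if (!length(prot_o)) stop("toy protein lacks a backbone carbonyl oxygen")
  xyz <- coords(complex)
  d_po <- sqrt(colSums((t(xyz[prot_o, , drop = FALSE]) - a_d)^2))
  ok <- which(d_po > 1.5 & d_po < 5.5)
  if (!length(ok))
    stop("no feasible water placement: no protein acceptor within 5.5 A ",
         "of the DNA acceptor (site buried)")
  a_p <- xyz[prot_o[ok[which.min(d_po[ok])]], ]
  mid <- (a_d + a_p) / 2
  half <- vec_norm(a_d - a_p) / 2
  h <- sqrt(2.8^2 - half^2)
  axis <- unit(a_d - a_p)
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp1 <- unit(ref - sum(ref * axis) * axis)
  perp2 <- as.numeric(c(axis[2] * perp1[3] - axis[3] * perp1[2],
                        axis[3] * perp1[1] - axis[1] * perp1[3],
                        axis[1] * perp1[2] - axis[2] * perp1[1]))
  cands <- lapply(list(perp1, -perp1, perp2, -perp2),
                  function(p) mid + h * p)
  clearance <- vapply(cands, function(ow)
    min(sqrt(colSums((t(xyz) - ow)^2))), numeric(1))
  ow <- cands[[which.max(clearance)]]
  if (max(clearance) < 2.0)
    stop("no feasible water placement: site is sterically buried")
  hw1 <- ow + NH_BOND * unit(a_d - ow)
  hw2 <- ow + NH_BOND * unit(a_p - ow)
  wat <- data.frame(serial = NA_integer_, name = c("OW", "HW1", "HW2"),
                    element = c("O", "H", "H"), res_name = WATER_RESIDUE,
                    res_seq = 1L, chain_id = "W",
                    x = c(ow[1], hw1[1], hw2[1]),
                    y = c(ow[2], hw1[2], hw2[2]),
                    z = c(ow[3], hw1[3], hw2[3]), record = "HETATM",
                    stringsAsFactors = FALSE)
  atoms <- rbind(a, wat)
  atoms$serial <- seq_len(nrow(atoms))
  s <- pdb_structure(atoms, title = paste(complex$title, "+ bridging water"))
  attr(s, "sequence") <- attr(complex, "sequence")
  attr(s, "site") <- attr(complex, "site")
  s
}

#' Simulate a toy trajectory by positional noise
#'
#' Frames are the base coordinates plus independent isotropic Gaussian
#' displacements of scale `sigma` per heavy atom per frame; hydrogens ride
#' their parent heavy atom (same displacement), keeping donor-hydrogen
#' geometry chemically sane.  This is a stand-in for an MD production run,
#' not an MD engine: there is no force field, only a controllable
#' positional fluctuation amplitude.
#'
#' @param base a [pdb_structure].
#' @param sigma per-coordinate displacement scale, Angstrom (>= 0).
#' @param n_frames number of frames.
#' @param dt_ps frame spacing, ps.
#' @param seed integer seed (reproducible).
#' @param run_id replicate identifier stored in the trajectory.
#' @return an [md_trajectory].
#' @export
simulate_trajectory <- function(base, sigma = 0.5, n_frames = 100L,
                                dt_ps = 50, seed = 1L, run_id = NULL) {
  stopifnot(inherits(base, "pdb_structure"))
  if (sigma < 0) stop("sigma must be >= 0")
  xyz <- coords(base)
  n <- nrow(xyz)
  is_h <- toupper(base$atoms$element) == "H"
  heavy <- which(!is_h)
  parent <- integer(n)
  parent[heavy] <- heavy
  if (any(is_h)) {
    for (i in which(is_h)) {
      d2 <- colSums((t(xyz[heavy, , drop = FALSE]) - xyz[i, ])^2)
      parent[i] <- heavy[which.min(d2)]
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (m in seq_len(n_frames)) {
    disp <- matrix(0, n, 3)
    disp[heavy, ] <- matrix(stats::rnorm(length(heavy) * 3L, sd = sigma),
                            length(heavy), 3)
    frames[[m]] <- xyz + disp[parent, , drop = FALSE]
  }
  md_trajectory(base, frames, dt_ps = dt_ps, run_id = run_id)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate an AR(1) interaction-energy series
#'
#' Both channels are independent stationary AR(1) processes
#' `x_t = mu + phi (x_{t-1} - mu) + eps_t` with innovation variance
#' `sigma^2 (1 - phi^2)`, so the marginal standard deviation is `sigma` --
#' emulating the autocorrelation of MD interaction-energy samples.
#'
#' @param mean_vdw,mean_el stationary means, kcal/mol.
#' @param sigma_vdw,sigma_el stationary standard deviations, kcal/mol.
#' @param phi lag-1 autocorrelation, |phi| < 1.
#' @param n number of samples.
#' @param variant,environment system labels (see [energy_series()]).
#' @param seed integer seed.
#' @param sample_interval_ps sample spacing, ps.
#' @return an [energy_series].
#' @export
simulate_energy_series <- function(mean_vdw, mean_el, sigma_vdw = 1.5,
                                   sigma_el = 3.0, phi = 0.9, n = 10000L,
                                   variant = "AT", environment = "Complex",
                                   seed = 1L, sample_interval_ps = 0.02) {
  if (abs(phi) >= 1) stop("phi must satisfy |phi| < 1")
  if (sigma_vdw < 0 || sigma_el < 0) stop("sigmas must be >= 0")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ar1 <- function(mu, sigma) {
    if (sigma == 0) return(rep(mu, n))
    x0 <- stats::rnorm(1, 0, sigma)
    eps <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
    mu + as.numeric(stats::filter(eps, phi, method = "recursive",
                                  init = x0))
  }
  energy_series(variant, environment, e_vdw = ar1(mean_vdw, sigma_vdw),
                e_el = ar1(mean_el, sigma_el),
                sample_interval_ps = sample_interval_ps)
}

# Named preset definitions.  "paper_default" encodes the studied regime:
# a relative binding free energy of -0.800 kcal/mol dominated by the
# electrostatic term (component split -0.700 el / -0.100 vdW), realised by
# shifting only the GC-Complex cell relative to an otherwise null cycle,
# and substituted-pair trajectories 0.7x as mobile as wild-type ones.
# "null" is the exactly symmetric control: identical energy cells and
# identical derived seeds for both variants.
preset_definition <- function(name) {
  name <- match.arg(name, c("paper_default", "null"))
  base_complex <- c(vdw = -100, el = -200)
  base_dna <- c(vdw = -90, el = -180)
  means <- list(
    AT.Complex = base_complex, AT.DNA = base_dna,
    GC.Complex = base_complex, GC.DNA = base_dna)
  if (name == "paper_default") {
    means$GC.Complex <- base_complex + c(vdw = -0.10 / 0.18,
                                         el = -0.70 / 0.43)
  }
  list(name = name, means = means, sigma_vdw = 1.5, sigma_el = 3.0,
       phi = 0.9, n_runs = 16L, n_samples = 10000L,
       sequence = "GCATG", site = 3L,
       # in the null control the "substitution" is the identity swap, so
       # the two variants are structurally identical as well
       mutant_pair = if (name == "paper_default") "GC" else "AT",
       sigma_traj_wt = 0.5,
       sigma_traj_mut = if (name == "paper_default") 0.35 else 0.5,
       n_frames = 100L, dt_ps = 50, sample_interval_ps = 0.02,
       share_variant_seed = (name == "null"))
}

#' Noiseless mean energies of a preset
#'
#' @param name `"paper_default"` or `"null"`.
#' @return list of four [mean_energies] (zero standard errors), on which
#'   [ddg_bind()] reproduces the preset's generating ddG exactly.
#' @export
preset_means <- function(name = "paper_default") {
  def <- preset_definition(name)
  lapply(names(def$means), function(cell) {
    parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
    mean_energies(parts[1], parts[2], mean_vdw = def$means[[cell]][["vdw"]],
                  mean_el = def$means[[cell]][["el"]])
  })
}

#' Generate a complete four-system synthetic dataset
#'
#' Builds everything the pipeline consumes: the wild-type and substituted
#' duplexes and toy complexes (with bridging water), replicate noise
#' trajectories for the four systems, and replicate AR(1) energy series
#' for the four cells of the thermodynamic cycle.
#'
#' @param name `"paper_default"` (ddG -0.800 kcal/mol, electrostatically
#'   dominated; mutant 0.7x wild-type mobility) or `"null"` (exactly
#'   symmetric control).
#' @param seed master seed; all replicate streams derive from it.
#' @param components subset of `c("structures", "trajectories",
#'   "energies")` to generate.
#' @return list with `structures` (dna_AT, dna_GC, complex_AT, complex_GC),
#'   `trajectories` (same names; each a list of `n_runs`
#'   [md_trajectory]s), `energies` (list of runs, each the four
#'   [energy_series]), `definition` and `seed`.
#' @export
synthetic_preset <- function(name = "paper_default", seed = 42L,
                             components = c("structures", "trajectories",
                                            "energies")) {
  def <- preset_definition(name)
  components <- match.arg(components, several.ok = TRUE)
  wt <- build_duplex(def$sequence)
  mut <- mutate_pair(wt, def$site, def$mutant_pair)
  structures <- list(
    dna_AT = wt, dna_GC = mut,
    complex_AT = place_bridging_water(build_toy_complex(wt, def$site),
                                      def$site),
    complex_GC = place_bridging_water(build_toy_complex(mut, def$site),
                                      def$site))
  out <- list(definition = def, seed = seed,
              structures = if ("structures" %in% components) structures)
  if ("trajectories" %in% components) {
    out$trajectories <- lapply(names(structures), function(sys) {
      variant <- sub("^.*_", "", sys)
      environment <- if (grepl("^complex", sys)) "Complex" else "DNA"
      sigma <- if (variant == "GC") def$sigma_traj_mut else def$sigma_traj_wt
      lapply(seq_len(def$n_runs), function(run) {
        sd_args <- if (def$share_variant_seed) list(seed, "traj", environment, run)
                   else list(seed, "traj", variant, environment, run)
        simulate_trajectory(structures[[sys]], sigma = sigma,
                            n_frames = def$n_frames, dt_ps = def$dt_ps,
                            seed = do.call(derive_seed, sd_args),
                            run_id = run)
      })
    })
    names(out$trajectories) <- names(structures)
  }
  if ("energies" %in% components) {
    cells <- names(def$means)
    out$energies <- lapply(seq_len(def$n_runs), function(run) {
      runset <- lapply(cells, function(cell) {
        parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
        sd_args <- if (def$share_variant_seed)
          list(seed, "energy", parts[2], run)
        else list(seed, "energy", parts[1], parts[2], run)
        simulate_energy_series(
          mean_vdw = def$means[[cell]][["vdw"]],
          mean_el = def$means[[cell]][["el"]],
          sigma_vdw = def$sigma_vdw, sigma_el = def$sigma_el,
          phi = def$phi, n = def$n_samples, variant = parts[1],
          environment = parts[2], seed = do.call(derive_seed, sd_args),
          sample_interval_ps = def$sample_interval_ps)
      })
      names(runset) <- cells
      runset
    })
  }
  out
}
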