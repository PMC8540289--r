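## Fixture factory emulating the full experimental design: a grid of
## stopped-flow shrinkage runs (composition x osmotic difference x
## temperature x solute x replicate), flicker-microscopy contour series per
## composition, and the six-curve proton-flux condition set. Every file
## round-trips bit-exactly through the io layer and every ground-truth
## parameter is recorded in a manifest, so estimator recovery errors can be
## computed without reaching back into generator internals.

#' Default membrane composition table
#'
#' Bending rigidities and composition effect multipliers for the four
#' synthetic membrane compositions. These are package defaults chosen to
#' reproduce the qualitative composition effects (cholesterol stiffens the
#' membrane and raises the pore-opening delay tenfold amplifying the
#' stage-II/III optical rise; lysoPC softens it; PE leaves rigidity unchanged
#' but raises the water permeability by 1.2x) -- they are defaults, not
#' measurements.
#'
#' @return Data frame with columns `composition`, `kappa_b_kbt`, `p_mult`,
#'   `gamma_mult`.
#' @export
default_mechanics_table <- function() {
  data.frame(
    composition = c("PC", "PC/chol 7:3", "PC/lysoPC 7:3", "PC/PE 7:3"),
    kappa_b_kbt = c(25, 50, 15, 25),
    p_mult = c(1, 1, 1, 1.2),
    gamma_mult = c(1, 10, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Synthetic study design
#'
#' The experimental grid the fixture factory emulates: which compositions,
#' osmotic pressure differences, temperatures, solutes and replicate counts
#' to generate, plus the master seed from which every per-file seed is
#' derived deterministically (by hashing the condition label).
#'
#' @param compositions Character vector; must appear in `mechanics_table`.
#' @param delta_pi_mosm Osmotic pressure sweep, mOsm.
#' @param temperatures_k Temperatures, K.
#' @param solutes Solute labels (never enter any computation).
#' @param replicates Replicates per condition.
#' @param master_seed Master seed.
#' @param noise_sd_au Instrument noise sd for shrinkage traces, a.u.
#' @param flicker_n_frames Frames per flicker series.
#' @param sigma_bar Reduced tension of the flicker generator.
#' @param mean_radius_um GUV radius for flicker series, micrometres.
#' @param proton_noise_sd_au Noise sd for fluorescence traces, a.u.
#' @param mechanics_table See [default_mechanics_table()].
#' @param profile `"full"` or `"ci"`; `"ci"` shrinks the grid (3 osmotic
#'   differences, 1 replicate, 500 frames) so the whole bundle regenerates in
#'   well under a minute.
#' @return Object of class `"study_design"`.
#' @export
study_design <- function(compositions = default_mechanics_table()$composition,
                         delta_pi_mosm = c(15, 25, 50, 100, 150),
                         temperatures_k = 298.15,
                         solutes = "KCl",
                         replicates = 3,
                         master_seed = 20211014,
                         noise_sd_au = 0.02,
                         flicker_n_frames = 10000,
                         sigma_bar = 5,
                         mean_radius_um = 10,
                         proton_noise_sd_au = 0.2,
                         mechanics_table = default_mechanics_table(),
                         profile = c("full", "ci")) {
  profile <- match.arg(profile)
  if (profile == "ci") {
    # reduced grid; explicitly supplied values still win
    if (missing(delta_pi_mosm)) delta_pi_mosm <- c(15, 50, 150)
    if (missing(replicates)) replicates <- 1
    if (missing(flicker_n_frames)) flicker_n_frames <- 500
  }
  if (!length(delta_pi_mosm) || !length(temperatures_k) || !length(solutes) ||
      !length(compositions)) {
    stop_invalid("all design sweeps must be non-empty")
  }
  missing_comp <- setdiff(compositions, mechanics_table$composition)
  if (length(missing_comp)) {
    stop_invalid("compositions absent from mechanics table: ",
                 paste(missing_comp, collapse = ", "))
  }
  structure(
    list(compositions = compositions, delta_pi_mosm = delta_pi_mosm,
         temperatures_k = temperatures_k, solutes = solutes,
         replicates = replicates, master_seed = master_seed,
         noise_sd_au = noise_sd_au, flicker_n_frames = flicker_n_frames,
         sigma_bar = sigma_bar, mean_radius_um = mean_radius_um,
         proton_noise_sd_au = proton_noise_sd_au,
         mechanics_table = mechanics_table, profile = profile),
    class = "study_design"
  )
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9]+", "-", x)

write_manifest <- function(df, path, note = NULL) {
  header <- c("# osmoflux fixture manifest",
              "# ground-truth parameters are generator defaults, not measurements")
  if (!is.null(note)) header <- c(header, paste0("# ", note))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  ## numeric columns at full precision so recovery errors are exact
  df_out <- df
  for (j in seq_along(df_out)) {
    if (is.numeric(df_out[[j]])) df_out[[j]] <- sprintf("%.17g", df_out[[j]])
  }
  write.table(df_out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fixture manifest
#'
#' @param path Manifest path.
#' @return Data frame of per-file ground truth.
#' @export
read_manifest <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}

#' Generate the stopped-flow shrinkage fixture bundle
#'
#' One trace file per (composition, delta_pi, temperature, solute,
#' replicate). The pore-opening delay comes from the delay law
#' ([pore_delay_time()]) at the composition's bending rigidity; composition
#' effects follow the defaults of [default_mechanics_table()]. Seeds derive
#' from the master seed and the condition label, excluding the solute label:
#' the solute never enters any computation, so runs differing only in solute
#' are identical.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory (created if needed).
#' @param cal A [delay_calibration()].
#' @param phys_base Base physics ([shrinkage_physics()]); per-condition `t0`
#'   and permeability multipliers are applied on top.
#' @param optics_base Base optics ([optics_map()]).
#' @return Invisibly, the manifest data frame (also written to
#'   `out_dir/manifest.tsv`).
#' @export
make_shrinkage_dataset <- function(design, out_dir,
                                   cal = delay_calibration(),
                                   phys_base = shrinkage_physics(),
                                   optics_base = optics_map()) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mt <- design$mechanics_table
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      solute = design$solutes,
                      temperature_k = design$temperatures_k,
                      delta_pi_mosm = design$delta_pi_mosm,
                      composition = design$compositions,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    row_mt <- mt[mt$composition == g$composition, ]
    mech <- membrane_mechanics(row_mt$kappa_b_kbt,
                               temperature = g$temperature_k)
    cond <- osmotic_condition(g$delta_pi_mosm, solute = g$solute)
    t0 <- pore_delay_time(cond, mech, cal)$t0
    p <- phys_base$permeability * row_mt$p_mult
    gamma <- optics_base$gamma * row_mt$gamma_mult
    phys <- shrinkage_physics(permeability = p, t0 = t0,
                              k_mech = phys_base$k_mech)
    optics <- optics_map(optics_base$i_00, optics_base$i_0fin, gamma)
    ## solute deliberately left out of the seed label
    label <- paste("shrink", g$composition, g$delta_pi_mosm,
                   g$temperature_k, g$replicate, sep = "|")
    seed <- derive_seed(design$master_seed, label)
    tr <- simulate_shrinkage_trace(
      cond, phys, optics = optics, noise_sd = design$noise_sd_au,
      seed = seed, composition = g$composition,
      temperature = g$temperature_k)
    fname <- sprintf("%s_dpi%s_T%05.1f_%s_rep%d.tsv",
                     sanitize_label(g$composition),
                     sanitize_label(format(g$delta_pi_mosm)),
                     g$temperature_k, sanitize_label(g$solute), g$replicate)
    write_trace(tr, file.path(out_dir, fname))
    rows[[i]] <- data.frame(
      file = fname, composition = g$composition, solute = g$solute,
      delta_pi_mosm = g$delta_pi_mosm, temperature_k = g$temperature_k,
      replicate = g$replicate, seed = seed, t0_true_s = t0,
      p_true_m_per_s = p, gamma_au = gamma, k_mech_mosm = phys_base$k_mech,
      kappa_b_kbt = row_mt$kappa_b_kbt, i_00_au = optics_base$i_00,
      i_0fin_au = optics_base$i_0fin, noise_sd_au = design$noise_sd_au,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"),
                 note = "shrinkage traces")
  invisible(manifest)
}

#' Generate the flicker-microscopy fixture bundle
#'
#' Per composition: a Helfrich-distributed contour series at the
#' composition's default bending rigidity, written as a contour table;
#' optionally rendered into a multi-page TIFF stack (with dropout noise) and
#' re-extracted, with the extracted series written alongside.
#'
#' @param design A [study_design()] (`flicker_n_frames`, `sigma_bar`,
#'   `mean_radius_um` are used).
#' @param out_dir Output directory.
#' @param render Also render/extract image stacks (slower), default `FALSE`.
#' @return Invisibly, the manifest data frame.
#' @export
make_flicker_dataset <- function(design, out_dir, render = FALSE) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mt <- design$mechanics_table
  rows <- vector("list", length(design$compositions))
  for (i in seq_along(design$compositions)) {
    comp <- design$compositions[i]
    kappa <- mt$kappa_b_kbt[mt$composition == comp]
    seed <- derive_seed(design$master_seed, paste("flicker", comp, sep = "|"))
    mech <- membrane_mechanics(kappa)
    ctr <- generate_contours(design$mean_radius_um, mech,
                             sigma_bar = design$sigma_bar,
                             n_frames = design$flicker_n_frames, seed = seed)
    base <- sanitize_label(comp)
    ctr_file <- paste0(base, "_contours.tsv")
    write_contours(ctr, file.path(out_dir, ctr_file))
    tiff_file <- NA_character_
    extracted_file <- NA_character_
    pass_rate <- NA_real_
    if (render) {
      stack <- render_frames(ctr, seed = seed + 1L)
      tiff_file <- paste0(base, "_frames.tif")
      write_framestack(stack, file.path(out_dir, tiff_file))
      ext <- extract_contours(stack)
      extracted_file <- paste0(base, "_contours_extracted.tsv")
      write_contours(ext, file.path(out_dir, extracted_file))
      pass_rate <- mean(ext$flags)
    }
    rows[[i]] <- data.frame(
      composition = comp, contour_file = ctr_file, tiff_file = tiff_file,
      extracted_file = extracted_file, kappa_b_true_kbt = kappa,
      sigma_bar_true = design$sigma_bar,
      mean_radius_um = design$mean_radius_um,
      n_frames = design$flicker_n_frames, seed = seed,
      extraction_pass_rate = pass_rate, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"),
                 note = "flicker contour series")
  invisible(manifest)
}

#' Generate the proton-flux fixture bundle
#'
#' Replicates the six-curve condition set of the proton-flux experiment:
#' no gradients; osmotic difference only (15 mOsm, KCl and sucrose); pH
#' gradient 1.4 alone and combined with 15 and 150 mOsm.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory.
#' @param kin A [proton_kinetics()].
#' @param coupling See [proton_slow_slope()].
#' @return Invisibly, the manifest data frame.
#' @export
make_proton_dataset <- function(design, out_dir, kin = proton_kinetics(),
                                coupling = default_proton_coupling()) {
  stopifnot(inherits(design, "study_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- data.frame(
    curve = 1:6,
    delta_ph = c(0, 0, 0, 1.4, 1.4, 1.4),
    delta_pi = c(0, 15, 15, 0, 15, 150),
    solute = c("none", "KCl", "sucrose", "none", "KCl", "KCl"),
    stringsAsFactors = FALSE)
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cn <- conds[i, ]
    ## solute excluded from the seed label (it never enters the computation)
    label <- paste("proton", cn$delta_ph, cn$delta_pi, sep = "|")
    seed <- derive_seed(design$master_seed, label)
    cond <- osmotic_condition(cn$delta_pi, delta_ph = cn$delta_ph,
                              solute = cn$solute)
    tr <- simulate_fluorescence(kin, cond, coupling,
                                noise_sd = design$proton_noise_sd_au,
                                seed = seed)
    fname <- sprintf("curve%d_dph%.1f_dpi%03d_%s.tsv", cn$curve, cn$delta_ph,
                     cn$delta_pi, sanitize_label(cn$solute))
    write_trace(tr, file.path(out_dir, fname))
    rows[[i]] <- data.frame(
      file = fname, curve = cn$curve, delta_ph = cn$delta_ph,
      delta_pi_mosm = cn$delta_pi, solute = cn$solute, seed = seed,
      m_slow_true = tr$meta$m_slow_true,
      noise_sd_au = design$proton_noise_sd_au, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"),
                 note = "proton-flux fluorescence traces")
  invisible(manifest)
}

#' Generate the complete fixture bundle
#'
#' Creates `shrinkage/`, `flicker/` and `proton/` subdirectories under
#' `out_dir`, each with its manifest.
#'
#' @param design A [study_design()].
#' @param out_dir Output directory.
#' @param render_flicker Render flicker image stacks too, default `FALSE`.
#' @return Invisibly, a list of the three manifests.
#' @export
make_fixture_bundle <- function(design, out_dir, render_flicker = FALSE) {
  list(
    shrinkage = make_shrinkage_dataset(design, file.path(out_dir, "shrinkage")),
    flicker = make_flicker_dataset(design, file.path(out_dir, "flicker"),
                                   render = render_flicker),
    proton = make_proton_dataset(design, file.path(out_dir, "proton"))
  )
}
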