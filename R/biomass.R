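## Biomass-equation construction: macromolecular fractions + monomer
## composition tables -> normalized biomass pseudo-reaction (1 g per unit
## flux) and its elemental composition.
##
## All polymer monomers are residues (water of polymerization already
## subtracted), so no water is produced by the assembled equation.
## Polymerization energy is not itemized per bond; it is carried by the
## lumped GAM ATP term.

#' Monomer reference table
#'
#' Residue molar masses and elemental formulas for the biomass building
#' blocks: amino-acid residues, NMP/dNMP residues, lipid backbones and acyl
#' chains, the LPS aggregate, glycogen and peptidoglycan units, a cofactor
#' pool, and the ATP hydrolysis couple. The bundled table is
#' reference-derived (standard residue chemistry; the LPS and murein entries
#' are coarse aggregates) and editable: supply your own file with the same
#' columns to override it.
#'
#' @param path TSV with columns `id`, `class`, `name`, `formula`, `mass`;
#'   defaults to the bundled table.
#' @return data.frame with row names set to `id`.
#' @export
monomerTable <- function(path = system.file("extdata", "monomers.tsv",
                                            package = "fluxrecon")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "class", "formula", "mass")
  if (!all(need %in% names(df)))
    inputError("monomer table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id)) inputError("duplicate monomer ids")
  if (any(df$mass <= 0)) inputError("monomer masses must be positive")
  calc <- vapply(df$formula, formulaMass, numeric(1))
  off <- abs(calc - df$mass) / df$mass
  if (any(off > 0.001))
    inputError("monomer mass inconsistent with formula for: ",
               paste(df$id[off > 0.001], collapse = ", "))
  rownames(df) <- df$id
  df
}

.monomerMass <- function(monomers, ids) {
  missing_ids <- setdiff(ids, rownames(monomers))
  if (length(missing_ids))
    inputError("missing monomer entries: ", paste(missing_ids, collapse = ", "))
  stats::setNames(monomers[ids, "mass"], ids)
}

#' Assemble a closed macromolecular composition
#'
#' Applies the water-insoluble-protein increment and the peptidoglycan
#' constant to the measured fractions and closes the composition to a total
#' of 1 g/g. Under the `"remainder"` policy the unassigned mass becomes the
#' cofactor pool (an error if the fractions already exceed 1); under
#' `"proportional"` all fractions are rescaled to sum to 1 and the cofactor
#' pool is zero.
#'
#' @param measured Named numeric mass fractions (g/gDCW) with names among
#'   `soluble_protein`, `lipid`, `carbohydrate`, `rna`, `dna` (missing names
#'   count as zero).
#' @param insoluble_increment Water-insoluble protein added to the soluble
#'   protein fraction, in g/gDCW (default 0.122, i.e. 12.2 percentage
#'   points).
#' @param peptidoglycan Peptidoglycan mass fraction (default 0.086).
#' @param policy Closure policy, `"remainder"` or `"proportional"`.
#' @return Named numeric vector of class `MacromolecularComposition` with
#'   elements `protein`, `lipid`, `carbohydrate`, `rna`, `dna`,
#'   `peptidoglycan`, `cofactor_pool`, summing to 1.
#' @examples
#' assembleComposition(c(soluble_protein = 0.406, lipid = 0.084,
#'                       carbohydrate = 0.021, rna = 0.226, dna = 0.022))
#' @export
assembleComposition <- function(measured,
                                insoluble_increment = 0.122,
                                peptidoglycan = 0.086,
                                policy = c("remainder", "proportional")) {
  policy <- match.arg(policy)
  if (any(measured < 0) || insoluble_increment < 0 || peptidoglycan < 0)
    inputError("fractions must be non-negative")
  known <- c("soluble_protein", "lipid", "carbohydrate", "rna", "dna")
  extra <- setdiff(names(measured), known)
  if (length(extra))
    inputError("unknown fraction name(s): ", paste(extra, collapse = ", "))
  get0n <- function(nm) if (nm %in% names(measured)) measured[[nm]] else 0
  frac <- c(
    protein = get0n("soluble_protein") + insoluble_increment,
    lipid = get0n("lipid"),
    carbohydrate = get0n("carbohydrate"),
    rna = get0n("rna"),
    dna = get0n("dna"),
    peptidoglycan = peptidoglycan
  )
  total <- sum(frac)
  if (policy == "remainder") {
    if (total > 1 + 1e-9)
      inputError("fractions sum to ", round(total, 4),
                 " > 1; use policy = 'proportional' or revise the inputs")
    out <- c(frac, cofactor_pool = max(0, 1 - total))
  } else {
    out <- c(frac / total, cofactor_pool = 0)
  }
  structure(out, class = "MacromolecularComposition",
            soluble_protein = get0n("soluble_protein"),
            insoluble_increment = insoluble_increment)
}

#' @export
print.MacromolecularComposition <- function(x, ...) {
  cat("Macromolecular composition (g/gDCW):\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Amino-acid profiles and reference fill-in
#'
#' `putidaAminoAcidProfile()` returns the measured amino-acid mol% of
#' P. putida KT2440 protein at D = 0.2/h, with the assay's combined
#' Asx/Glx categories split equally between the acid and amide forms.
#' `fillAminoAcidProfile()` adds the amino acids a profile is missing
#' (typically Cys/Met/Trp, which standard hydrolysis assays destroy) at
#' reference mol% taken from the E. coli biomass, then renormalizes to
#' 100 mol%. Filling is idempotent: a complete profile is only renormalized.
#'
#' @param profile Named numeric mol% keyed by three-letter residue ids
#'   (lowercase, e.g. `ala`).
#' @param fillin Named numeric reference mol% for the missing residues.
#' @return Named numeric mol% summing to 100, with attribute `filled_in`
#'   naming the residues that were supplied from the reference.
#' @export
fillAminoAcidProfile <- function(profile,
                                 fillin = c(cys = 1.7, met = 2.9, trp = 1.1)) {
  if (any(profile < 0) || any(fillin < 0)) inputError("negative mol%")
  add <- setdiff(names(fillin), names(profile))
  prev <- attr(profile, "filled_in")
  out <- c(unclass(profile), fillin[add])
  out <- out / sum(out) * 100
  attr(out, "filled_in") <- union(prev, add)
  out
}

#' @rdname fillAminoAcidProfile
#' @export
putidaAminoAcidProfile <- function() {
  c(ala = 12, arg = 5, asp = 5, asn = 5, glu = 6, gln = 6, gly = 10,
    his = 2, ile = 4, leu = 10, lys = 5, phe = 4, pro = 5, ser = 5,
    thr = 5, tyr = 3, val = 7)
}

## shared normalization: fraction (g/g) at monomer mol fractions -> mmol/g
.polymerCoefficients <- function(fraction, molfrac, monomers) {
  if (fraction < 0) inputError("negative mass fraction")
  if (fraction == 0) return(stats::setNames(numeric(0), character(0)))
  molfrac <- molfrac / sum(molfrac)
  mass <- .monomerMass(monomers, names(molfrac))
  avg_mass <- sum(molfrac * mass)          # g/mol of the average residue
  fraction * 1000 * molfrac / avg_mass     # mmol per gDCW
}

#' Protein monomer coefficients
#'
#' Converts an amino-acid mol% profile and a protein mass fraction into
#' residue coefficients: `coef_aa = fraction * 1000 * molfrac_aa /
#' sum(molfrac * residue_mass)` (mmol/gDCW), using water-subtracted residue
#' masses.
#'
#' @param profile Named mol% (see [fillAminoAcidProfile()]).
#' @param protein_fraction Protein mass fraction (g/gDCW).
#' @param monomers Monomer table from [monomerTable()].
#' @return Named numeric coefficients (mmol/gDCW).
#' @export
proteinCoefficients <- function(profile, protein_fraction,
                                monomers = monomerTable()) {
  .polymerCoefficients(protein_fraction, unclass(profile)[names(profile)],
                       monomers)
}

#' DNA base composition from GC content or a genome sequence
#'
#' With a GC content, the paired-base model A=T=(1-gc)/2, G=C=gc/2 is used.
#' With a genome FASTA, base frequencies are counted directly (requires the
#' Biostrings package).
#'
#' @param gc GC content in \[0,1\].
#' @param fasta Path to a genome FASTA file.
#' @return Named mol fractions for `damp`, `dtmp`, `dgmp`, `dcmp`.
#' @export
dnaBaseComposition <- function(gc = NULL, fasta = NULL) {
  if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      inputError("reading a genome FASTA requires the Biostrings package")
    seqs <- Biostrings::readDNAStringSet(fasta)
    counts <- colSums(Biostrings::letterFrequency(seqs, c("A", "T", "G", "C")))
    frac <- counts / sum(counts)
    return(c(damp = unname(frac["A"]), dtmp = unname(frac["T"]),
             dgmp = unname(frac["G"]), dcmp = unname(frac["C"])))
  }
  if (is.null(gc) || gc < 0 || gc > 1)
    inputError("supply gc in [0,1] or a genome FASTA")
  c(damp = (1 - gc) / 2, dtmp = (1 - gc) / 2, dgmp = gc / 2, dcmp = gc / 2)
}

#' Nucleic-acid monomer coefficients
#'
#' Same normalization as [proteinCoefficients()], over NMP (RNA) or dNMP
#' (DNA) residues. The default RNA base composition is the E. coli
#' composition at D = 0.6/h (reference-derived).
#'
#' @param kind `"rna"` or `"dna"`.
#' @param fraction Mass fraction (g/gDCW).
#' @param base_composition Named mol fractions over the four residues; must
#'   sum to 1 (a tolerance of 1e-6 is allowed before renormalization).
#' @param monomers Monomer table.
#' @return Named numeric coefficients (mmol/gDCW).
#' @export
nucleicAcidCoefficients <- function(kind = c("rna", "dna"), fraction,
                                    base_composition = NULL,
                                    monomers = monomerTable()) {
  kind <- match.arg(kind)
  if (is.null(base_composition)) {
    base_composition <- if (kind == "rna")
      c(amp = 0.262, cmp = 0.200, gmp = 0.322, ump = 0.216)
    else dnaBaseComposition(gc = 0.615)
  }
  expect <- if (kind == "rna") c("amp", "cmp", "gmp", "ump")
            else c("damp", "dtmp", "dgmp", "dcmp")
  if (!setequal(names(base_composition), expect))
    inputError(kind, " composition must be named over: ",
               paste(expect, collapse = ", "))
  if (abs(sum(base_composition) - 1) > 1e-6)
    inputError("base fractions must sum to 1")
  .polymerCoefficients(fraction, base_composition, monomers)
}

#' Lipid coefficients
#'
#' Splits the lipid fraction into an LPS aggregate (at `lps_share` g/gDCW)
#' and phospholipids. Each phospholipid class consumes its diacyl-free
#' backbone plus acyl residues (2 per phospholipid, 4 for cardiolipin) drawn
#' from the fatty-acid mol fractions; class abundances follow the head-group
#' mol fractions.
#'
#' @param fraction Total lipid mass fraction (g/gDCW).
#' @param head_groups Named mol fractions over `pe_bb`, `clpn_bb`, `pg_bb`.
#' @param fatty_acids Named mol fractions over acyl ids in the monomer table.
#' @param lps_share LPS mass (g/gDCW), must not exceed `fraction`.
#' @param monomers Monomer table.
#' @return Named numeric coefficients (mmol/gDCW) over backbones, acyls and
#'   `lps`.
#' @export
lipidCoefficients <- function(fraction,
                              head_groups = c(pe_bb = 0.737, clpn_bb = 0.213,
                                              pg_bb = 0.049),
                              fatty_acids = c(acyl_160 = 0.30,
                                              acyl_161 = 0.35,
                                              acyl_181 = 0.35),
                              lps_share = 0.034,
                              monomers = monomerTable()) {
  if (abs(sum(head_groups / sum(head_groups)) - 1) > 1e-9 ||
      any(head_groups < 0) || any(fatty_acids < 0))
    inputError("invalid head-group or fatty-acid fractions")
  if (lps_share < 0 || lps_share > fraction + 1e-12)
    inputError("lps_share must lie in [0, fraction]")
  head_groups <- head_groups / sum(head_groups)
  fatty_acids <- fatty_acids / sum(fatty_acids)
  out <- stats::setNames(numeric(0), character(0))
  phospho <- fraction - lps_share
  if (phospho > 0) {
    n_acyl <- stats::setNames(ifelse(grepl("^clpn", names(head_groups)), 4, 2),
                              names(head_groups))
    bb_mass <- .monomerMass(monomers, names(head_groups))
    acyl_mass <- .monomerMass(monomers, names(fatty_acids))
    avg_acyl <- sum(fatty_acids * acyl_mass)
    species_mass <- bb_mass + n_acyl * avg_acyl
    class_coef <- phospho * 1000 * head_groups / sum(head_groups * species_mass)
    acyl_coef <- sum(class_coef * n_acyl) * fatty_acids
    out <- c(class_coef, acyl_coef)
  }
  if (lps_share > 0)
    out <- c(out, lps = lps_share * 1000 / .monomerMass(monomers, "lps")[["lps"]])
  out
}

#' Finalize a biomass equation
#'
#' Merges per-macromolecule coefficient sets, adds the growth-associated
#' maintenance term as `gam` ATP + H2O -> ADP + Pi, and validates that one
#' unit of flux consumes a net 1.000 g (+-1e-6 g) of monomer mass.
#'
#' @param parts List of named coefficient vectors (mmol/gDCW), e.g. from
#'   [proteinCoefficients()] and friends.
#' @param gam GAM in mmol ATP/gDCW.
#' @param monomers Monomer table supplying residue masses and formulas.
#' @return A [BiomassEquation-class].
#' @export
finalizeEquation <- function(parts, gam = 0, monomers = monomerTable()) {
  if (gam < 0) inputError("gam must be >= 0")
  merged <- numeric(0)
  for (p in parts) {
    for (nm in names(p)) {
      merged[nm] <- (if (nm %in% names(merged)) merged[[nm]] else 0) + p[[nm]]
    }
  }
  if (any(merged < 0)) inputError("negative coefficients")
  consumed <- merged
  produced <- stats::setNames(numeric(0), character(0))
  if (gam > 0) {
    for (nm in c("atp", "h2o"))
      consumed[nm] <- (if (nm %in% names(consumed)) consumed[[nm]] else 0) + gam
    produced <- c(adp = gam, pi = gam)
  }
  species <- union(names(consumed), names(produced))
  mass <- .monomerMass(monomers, species)
  formula <- stats::setNames(monomers[species, "formula"], species)
  net_g <- (sum(consumed * mass[names(consumed)]) -
              sum(produced * mass[names(produced)])) / 1000
  if (abs(net_g - 1) > 1e-6)
    inputError("biomass equation mass check failed: net consumed mass = ",
               format(net_g, digits = 10), " g per unit flux")
  methods::new("BiomassEquation",
    consumed = consumed, produced = produced, gamATP = as.numeric(gam),
    speciesMass = mass, speciesFormula = formula
  )
}

#' @rdname biomassMass
#' @export
setGeneric("biomassMass", function(x) standardGeneric("biomassMass"))
#' Net consumed mass of a biomass equation
#'
#' @param x A [BiomassEquation-class].
#' @return Net consumed monomer mass in g per unit flux (1.000 by
#'   construction).
#' @export
setMethod("biomassMass", "BiomassEquation", function(x) {
  (sum(x@consumed * x@speciesMass[names(x@consumed)]) -
     sum(x@produced * x@speciesMass[names(x@produced)])) / 1000
})

#' Elemental composition of a biomass equation
#'
#' Mass fractions (% w/w) of C, H, N, O, P, S in the assembled biomass,
#' computed from the monomer formulas. The mass-neutral GAM couple is
#' excluded.
#'
#' @param eq A [BiomassEquation-class].
#' @return Named numeric percent mass fractions.
#' @export
elementalComposition <- function(eq) {
  consumed <- eq@consumed
  produced <- eq@produced
  gam <- eq@gamATP
  if (gam > 0) {
    consumed[c("atp", "h2o")] <- consumed[c("atp", "h2o")] - gam
    produced[c("adp", "pi")] <- produced[c("adp", "pi")] - gam
  }
  consumed <- consumed[consumed > 0]
  produced <- produced[produced > 0]
  missing_f <- !nzchar(eq@speciesFormula[names(c(consumed, produced))])
  if (any(missing_f))
    inputError("species lack formulas: ",
               paste(names(c(consumed, produced))[missing_f], collapse = ", "))
  atoms <- sumFormulas(eq@speciesFormula[names(consumed)], consumed)
  if (length(produced)) {
    patoms <- sumFormulas(eq@speciesFormula[names(produced)], produced)
    for (el in names(patoms))
      atoms[el] <- (if (el %in% names(atoms)) atoms[[el]] else 0) - patoms[[el]]
  }
  am <- fluxreconConstants$atomic_masses
  els <- intersect(names(am), names(atoms))
  out <- stats::setNames(rep(0, length(am)), names(am))
  out[els] <- atoms[els] * am[els] / 1000 * 100  # mmol*g/mol /1000 -> g; % of 1 g
  out
}

#' Build the P. putida KT2440 biomass equation
#'
#' Convenience wrapper assembling the full composition (measured
#' macromolecular fractions with the insoluble-protein and peptidoglycan
#' additions, measured amino-acid profile with reference fill-in,
#' genome-derived DNA composition, reference RNA and lipid compositions,
#' glycogen carbohydrate and a cofactor pool carrying the closure remainder)
#' into a normalized [BiomassEquation-class].
#'
#' @param gam GAM ATP term (mmol/gDCW), default 85.
#' @param gc Genomic GC content used for the DNA composition.
#' @param composition A `MacromolecularComposition`; defaults to the
#'   measured KT2440 composition at D = 0.2/h.
#' @param aa_profile Amino-acid mol% before fill-in.
#' @param monomers Monomer table.
#' @param lps_share LPS mass fraction within the lipids (g/gDCW).
#' @return A [BiomassEquation-class].
#' @examples
#' eq <- buildPutidaBiomass(gam = 85)
#' biomassMass(eq)           # 1.000 g per unit flux
#' elementalComposition(eq)  # percent C, H, N, O, P, S
#' @export
buildPutidaBiomass <- function(gam = 85, gc = 0.615,
                               composition = putidaComposition(),
                               aa_profile = putidaAminoAcidProfile(),
                               monomers = monomerTable(),
                               lps_share = 0.034) {
  aa <- fillAminoAcidProfile(aa_profile)
  cofactors <- rownames(monomers)[monomers$class == "cofactor"]
  pool_each <- composition[["cofactor_pool"]] / length(cofactors)
  pool <- stats::setNames(
    pool_each * 1000 / monomers[cofactors, "mass"], cofactors)
  parts <- list(
    proteinCoefficients(aa, composition[["protein"]], monomers),
    nucleicAcidCoefficients("rna", composition[["rna"]], monomers = monomers),
    nucleicAcidCoefficients("dna", composition[["dna"]],
                            dnaBaseComposition(gc = gc), monomers),
    lipidCoefficients(composition[["lipid"]], lps_share = lps_share,
                      monomers = monomers),
    c(glycogen = composition[["carbohydrate"]] * 1000 /
        monomers["glycogen", "mass"]),
    c(murein = composition[["peptidoglycan"]] * 1000 /
        monomers["murein", "mass"]),
    pool
  )
  finalizeEquation(parts, gam = gam, monomers = monomers)
}

#' @rdname buildPutidaBiomass
#' @export
putidaComposition <- function() {
  ## Table-1 totals: protein 52.8% (soluble 40.6 + 12.2 insoluble), lipid
  ## 8.4%, carbohydrate 2.1%, RNA 22.6%, DNA 2.2%, plus peptidoglycan 8.6%.
  assembleComposition(
    c(soluble_protein = 0.406, lipid = 0.084, carbohydrate = 0.021,
      rna = 0.226, dna = 0.022),
    insoluble_increment = 0.122, peptidoglycan = 0.086, policy = "remainder"
  )
}

#' Read macromolecular composition / amino-acid tables
#'
#' `readCompositionTable()` reads a two-column TSV (`macromolecule`,
#' `percent`) of measured fractions; `readAminoAcidTable()` reads a TSV
#' (`amino_acid`, `molpct`) where `Asx`/`Glx` are split equally into the
#' acid/amide residues and `NA` marks residues to be filled from reference.
#'
#' @param path File path.
#' @return Named numeric vector (fractions g/g, or mol%).
#' @export
readCompositionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  map <- c(protein = "soluble_protein", soluble_protein = "soluble_protein",
           lipid = "lipid", carbohydrate = "carbohydrate", rna = "rna",
           dna = "dna")
  key <- map[tolower(df$macromolecule)]
  if (any(is.na(key))) inputError("unknown macromolecule in table")
  stats::setNames(df$percent / 100, unname(key))
}

#' @rdname readCompositionTable
#' @export
readAminoAcidTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[!is.na(df$molpct), ]
  out <- numeric(0)
  for (i in seq_len(nrow(df))) {
    aa <- tolower(df$amino_acid[[i]])
    v <- df$molpct[[i]]
    if (aa == "asx") { out["asp"] <- v / 2; out["asn"] <- v / 2 }
    else if (aa == "glx") { out["glu"] <- v / 2; out["gln"] <- v / 2 }
    else out[aa] <- v
  }
  out
}
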