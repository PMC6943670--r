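#' Aggregate MM/GBSA energy components into a binding free energy
#'
#' Bookkeeping of the standard decomposition: the gas-phase interaction
#' energy \code{dE_gas = dE_vdw + dE_ele}, the solvation free energy
#' \code{dG_sol = dG_gb + dG_sa}, and the binding free energy
#' \code{dG_bind = dE_gas + dG_sol - TdS}.  The entropy term is routinely
#' omitted from snapshot MM/GBSA runs and defaults to absent (treated as 0);
#' when per-species raw totals are supplied they are only used as a
#' consistency check against \code{dG_complex - dG_protein - dG_ligand}.
#'
#' @param components One-row data frame or named list with \code{dE_ele},
#'   \code{dE_vdw}, \code{dG_gb}, \code{dG_sa} (kcal/mol); optional
#'   \code{t_dS}, \code{complex_id}, \code{pic50}, and raw totals
#'   \code{raw_complex}, \code{raw_protein}, \code{raw_ligand}.
#' @return One-row data frame with \code{dE_gas}, \code{dG_sol},
#'   \code{dG_bind} alongside the inputs.
#' @export
aggregate_binding_energy <- function(components) {
  ec <- as.list(components)
  for (f in c("dE_ele", "dE_vdw", "dG_gb", "dG_sa")) {
    if (is.null(ec[[f]]) || is.na(ec[[f]]))
      stop("missing energy component '", f, "'")
    if (!is.finite(ec[[f]])) stop("non-finite energy component '", f, "'")
  }
  t_ds <- if (!is.null(ec$t_dS) && !is.na(ec$t_dS)) ec$t_dS else 0
  de_gas <- ec$dE_vdw + ec$dE_ele
  dg_sol <- ec$dG_gb + ec$dG_sa
  dg_bind <- de_gas + dg_sol - t_ds
  if (!is.null(ec$raw_complex) && !is.na(ec$raw_complex)) {
    raw <- ec$raw_complex - ec$raw_protein - ec$raw_ligand
    if (abs(raw - dg_bind) > 1e-3)
      stop(sprintf(
        "raw totals inconsistent with components: %.4f vs %.4f kcal/mol",
        raw, dg_bind))
  }
  data.frame(complex_id = if (!is.null(ec$complex_id)) ec$complex_id
                          else NA_character_,
             dE_ele = ec$dE_ele, dE_vdw = ec$dE_vdw,
             dG_gb = ec$dG_gb, dG_sa = ec$dG_sa,
             t_dS = if (!is.null(ec$t_dS) && !is.na(ec$t_dS)) ec$t_dS
                    else NA_real_,
             dE_gas = de_gas, dG_sol = dg_sol, dG_bind = dg_bind,
             pic50 = if (!is.null(ec$pic50)) ec$pic50 else NA_real_,
             stringsAsFactors = FALSE)
}

# header normalisation for component tables: case/punctuation-insensitive
.gbsa_aliases <- list(
  complex_id = c("complexid", "id", "no", "compound", "complex", "name"),
  dE_ele = c("deele", "dele", "ele", "eel", "elec", "electrostatic"),
  dE_vdw = c("devdw", "dvdw", "vdw", "vdwaals"),
  dG_gb = c("dggb", "dgb", "gb", "egb", "polar"),
  dG_sa = c("dgsa", "dsa", "sa", "esurf", "nonpolar"),
  t_dS = c("tds", "tdels", "entropy"),
  dG_sol = c("dgsol", "dsol", "sol", "gsol"),
  dG_bind = c("dgbind", "dbind", "bind", "gbind", "deltatotal"),
  pic50 = c("pic50", "pic"),
  raw_complex = c("rawcomplex", "gcomplex"),
  raw_protein = c("rawprotein", "gprotein", "greceptor"),
  raw_ligand = c("rawligand", "gligand"))

#' Read an MM/GBSA per-complex component table
#'
#' Delimited text (comma or tab, auto-detected) with a header naming the
#' energy components; header matching is case- and punctuation-insensitive
#' and accepts common AMBER spellings.  Unicode minus signs are mapped to
#' ASCII before numeric parsing; units are assumed kcal/mol.
#'
#' @param path File path.
#' @return Data frame of components, one row per complex (possibly empty).
#' @export
read_component_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- gsub("−", "-", lines)    # Unicode minus
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(data.frame())
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) return(data.frame())
  norm <- gsub("[^a-z0-9]", "", tolower(names(df)))
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (field in names(.gbsa_aliases)) {
    hit <- which(norm %in% c(gsub("[^a-z0-9]", "", tolower(field)),
                             .gbsa_aliases[[field]]))
    if (length(hit)) {
      col <- df[[hit[1]]]
      if (field != "complex_id") {
        parsed <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(parsed) & !is.na(col) & nzchar(trimws(col)))
        if (length(bad))
          stop("unparseable numeric in column '", names(df)[hit[1]],
               "', data row ", bad[1])
        col <- parsed
      } else col <- as.character(col)
      out[[field]] <- col
    }
  }
  out
}

#' Rank agreement between binding free energies and activities
#'
#' Complexes are ranked by ascending binding free energy (more negative =
#' stronger predicted binder) and by descending pIC50; the ranking is
#' concordant when the two orders are identical.  Spearman's rho is
#' computed between \code{-dG_bind} and \code{pIC50}, so perfect
#' concordance gives +1.  Ties are broken by complex id.
#'
#' @param records Data frame with \code{complex_id}, \code{dG_bind},
#'   \code{pic50} (>= 3 rows).
#' @return List with the two rank orders (complex ids), \code{concordant},
#'   and \code{spearman_rho}.
#' @export
rank_agreement <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("complex_id", "dG_bind", "pic50")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  r <- records[!is.na(records$pic50), , drop = FALSE]
  if (nrow(r) < 3) stop("need >= 3 complexes with pIC50")
  energy_order <- r$complex_id[order(r$dG_bind, r$complex_id)]
  activity_order <- r$complex_id[order(-r$pic50, r$complex_id)]
  list(energy_rank = energy_order,
       activity_rank = activity_order,
       concordant = identical(energy_order, activity_order),
       spearman_rho = stats::cor(-r$dG_bind, r$pic50, method = "spearman"))
}
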