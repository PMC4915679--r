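# Maintenance script: regenerates the packaged synthetic reference panels.
# One-off generator for the packaged synthetic reference panels.
# Writes inst/extdata/opsin_panel_synthetic.faa, opsin_panel_alignment_synthetic.faa,
# crt_panel_synthetic.faa. Frozen outputs are committed; rerun only to regenerate.
set.seed(20160621)

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
# rough natural amino-acid background, membrane-protein flavored (hydrophobic-rich)
w <- c(A=8.9,C=1.2,D=4.5,E=4.7,F=5.2,G=7.8,H=2.0,I=6.5,K=3.5,L=10.8,
       M=2.6,N=3.6,P=4.4,Q=3.2,R=4.4,S=6.3,T=5.8,V=7.8,W=2.4,Y=4.4)
w <- w[AA] / sum(w[AA])

L <- 230
schema <- c(`51`="Y", `72`="R", `76`="W", `108`="V", `127`="F", `171`="W",
            `174`="Y", `178`="W", `189`="D", `199`="Y", `216`="K")
pos <- as.integer(names(schema))

backbone <- sample(AA, L, replace = TRUE, prob = w)
backbone[pos] <- schema

mutate <- function(seq, rate, protect) {
  n <- length(seq)
  idx <- setdiff(which(runif(n) < rate), protect)
  for (i in idx) seq[i] <- sample(setdiff(AA, seq[i]), 1, prob = w[setdiff(AA, seq[i])])
  seq
}

fams <- c("BR", "BR2", "HR", "SRI", "SRII", "SR3", "MR")
panel <- list()
for (f in fams) {
  if (f == "SRII") { panel[[f]] <- backbone; next }
  panel[[f]] <- mutate(backbone, 0.30, protect = pos)
}

descs <- c(BR  = "synthetic exemplar, bacteriorhodopsin family",
           BR2 = "synthetic exemplar, bacteriorhodopsin-2 family",
           HR  = "synthetic exemplar, halorhodopsin family",
           SRI = "synthetic exemplar, sensory rhodopsin I family",
           SRII = "synthetic exemplar, sensory rhodopsin II family (numbering reference)",
           SR3 = "synthetic exemplar, sensory rhodopsin 3 family",
           MR  = "synthetic exemplar, middle rhodopsin family")

write_fa <- function(seqs, path, descs) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    cat(sprintf(">%s %s\n", nm, descs[[nm]]), file = con)
    s <- paste(seqs[[nm]], collapse = "")
    cat(gsub("(.{60})", "\\1\n", s), "\n", sep = "", file = con)
  }
  close(con)
}

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_fa(panel, "inst/extdata/opsin_panel_synthetic.faa", descs)
# the panel sequences are equal-length by construction, so the reference
# "alignment" is the ungapped column-per-position matrix of the same sequences
write_fa(panel, "inst/extdata/opsin_panel_alignment_synthetic.faa", descs)

crt <- list()
crt_descs <- c(crtY = "synthetic exemplar, lycopene cyclase",
               brp  = "synthetic exemplar, bacterioopsin-related protein / blh beta-carotene dioxygenase",
               crtE = "synthetic exemplar, geranylgeranyl pyrophosphate synthase",
               crtB = "synthetic exemplar, phytoene synthase",
               crtI = "synthetic exemplar, phytoene desaturase")
for (g in names(crt_descs)) crt[[g]] <- sample(AA, 300, replace = TRUE, prob = w)
write_fa(crt, "inst/extdata/crt_panel_synthetic.faa", crt_descs)

# pairwise identity sanity
m <- sapply(panel, identity)
for (i in 1:6) for (j in (i+1):7)
  cat(fams[i], fams[j], mean(m[, i] == m[, j]), "\n")
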