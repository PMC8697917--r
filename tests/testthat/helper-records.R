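# shared fixtures built in code

# a fully measured, internally consistent specimen (loosely based on the
# K. sefcae summaries, but a synthetic individual)
full_specimen <- function(id = "w1", host = "Odaxothrissa losera") {
  specimen_record(
    id, species_label = "K. sefcae", host_species = host,
    locality = "Pool Malebo", country = "DRC",
    da_total = 39, da_ltn = 29.3, da_inner = 21.6, da_outer = 6.2,
    da_point = 12.3,
    va_total = 45.1, va_ltn = 30, va_inner = 26, va_outer = 8.1,
    va_point = 12.8,
    db_len = 29.3, db_width = 8.5, vb_len = 27.4, vb_width = 8.5,
    hI = 15.7, hII = 17, hIII = 17, hIV = 16.4, hV = 17.8, hVI = 18,
    hVII = 18.4, mco_tube = 40.6, mco_ap = 44.8, ap_side = "left")
}

scale_specimen <- function(rec, c) {
  for (p in kg_params()) rec[[p]] <- rec[[p]] * c
  rec
}
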