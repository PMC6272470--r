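# Lectin family definitions: which domain accessions mark membership of each
# of the twelve plant lectin families, a reference length (aa) for the
# carbohydrate recognition domain, and the fraction of that length below
# which a hit is flagged as truncated.
#
# Pfam accessions are used where the family's lectin domain has one; the
# EUL, Nictaba and CRA domains have no dedicated Pfam entry and carry
# synthetic placeholder accessions (SYNDOM_*) that alignment-derived hit
# tables are expected to use.
families:
  ABA:
    accessions: [PF07367]
    reference_domain_length: 140
    truncation_fraction: 0.75
  amaranthin:
    accessions: [PF07468]
    reference_domain_length: 150
    truncation_fraction: 0.75
  CRA:
    accessions: [SYNDOM_CRA]
    reference_domain_length: 335
    truncation_fraction: 0.75
  cyanovirin:
    accessions: [PF08881]
    reference_domain_length: 100
    truncation_fraction: 0.75
  EUL:
    accessions: [SYNDOM_EUL]
    reference_domain_length: 150
    truncation_fraction: 0.75
  GNA:
    accessions: [PF01453]
    reference_domain_length: 110
    truncation_fraction: 0.75
  hevein:
    accessions: [PF00187]
    reference_domain_length: 40
    truncation_fraction: 0.75
  jacalin:
    accessions: [PF01419]
    reference_domain_length: 135
    truncation_fraction: 0.75
  legume:
    accessions: [PF00139]
    reference_domain_length: 230
    truncation_fraction: 0.75
  LysM:
    accessions: [PF01476]
    reference_domain_length: 45
    truncation_fraction: 0.75
  Nictaba:
    accessions: [SYNDOM_NICTABA]
    reference_domain_length: 145
    truncation_fraction: 0.75
  ricin B:
    accessions: [PF00652]
    reference_domain_length: 120
    truncation_fraction: 0.75

# Controlled vocabulary for non-lectin domains: accession -> architecture
# token and a typical length (aa) used by the synthetic-genome simulator.
tokens:
  PF00069: {token: kinase, length: 250}
  PF00954: {token: Slocus, length: 120}
  PF08276: {token: PAN, length: 80}
  PF01582: {token: TIR, length: 160}
  PF00931: {token: NB-ARC, length: 230}
  PF00560: {token: LRR, length: 60}
  PF00314: {token: thaumatin, length: 200}
  PF00967: {token: Barwin, length: 120}
  PF00150: {token: GH5, length: 300}
  PF00704: {token: GH18, length: 320}
  PF00182: {token: chitinase, length: 230}
  PF16499: {token: GH27, length: 280}
  PF00646: {token: F-box, length: 45}
  PF07059: {token: EEIG1, length: 200}
  PF00078: {token: RT, length: 180}
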