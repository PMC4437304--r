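PMID- 1000001
TI  - EGFR signaling in glioma progression
AB  - We study EGFR and TP53 in glioma. Erlotinib treatment altered
      apoptosis in tumor cells.
AU  - Bigner DD
AU  - Friedman HS
AD  - Department of Neurosurgery, Duke University, Durham, USA.
DP  - 2013 Jun

PMID- 1000002
TI  - Temozolomide response and MGMT methylation
AB  - MGMT methylation predicts temozolomide response in glioblastoma.
AU  - Sharma A
AD  - Institute of Chemical Biology, Kolkata, India.
DP  - 2014

PMID- 1000003
TI  - A mouse model of brain tumor
AB  - We characterize p53 loss in a mouse glioma model with EGFR
      amplification.
AU  - Tanaka K
AU  - Sato Y
AD  - Graduate School of Medicine, Tokyo, Japan.
DP  - 2012 Jan
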