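- name: core
  role: core
  formula: C12H20Si
  multiplicity: 4
  token: core
  smiles: '[Si]({*})({*})({*}){*}'
  notes: tetraallylsilane, tetravalent silicon branching centre
- name: AB3
  role: branch
  formula: C19H26O3Si
  multiplicity: 3
  coupling_delta: H3ClO
  token: '3'
  smiles: C(=O)c1ccc(OCCC[Si]({*})({*}){*})cc1
  notes: para-alkoxybenzoic acid with one triallylsilylpropyl wedge
- name: AB6
  role: branch
  formula: C31H46O4Si2
  multiplicity: 6
  coupling_delta: H3ClO
  token: '6'
  smiles: C(=O)c1cc(OCCC[Si]({*})({*}){*})cc(OCCC[Si]({*})({*}){*})c1
  notes: 3,5-bis-alkoxybenzoic acid with two triallylsilylpropyl wedges
- name: CA
  role: cap
  formula: C2H8ClNS
  multiplicity: 1
  token: 'N'
  notes: cysteamine hydrochloride; adds across terminal allyls by thiol-ene click
- name: BtO-AB3
  role: branch
  formula: C25H29N3O3Si
  multiplicity: 3
  coupling_delta: H3ClO
  token: 3bt
  notes: benzotriazol-1-yl activated ester of AB3 (acid OH replaced by OBt)
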