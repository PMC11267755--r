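# PAO1 pyoverdine scaffold: chromophore-acyl + 8 residues, macrolactam 5..8
residues: [Ser, Arg, Ser, fOHOrn, Lys, fOHOrn, Thr, Thr]
chromophore: ChrSuc
side_chain_form: succinate
cycle_span: [5, 8]
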