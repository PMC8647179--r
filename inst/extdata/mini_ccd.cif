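data_mini_ccd
# Synthetic mini component dictionary: a small stand-in for the archive's
# chemical component dictionary, covering common ligands/ions for
# nomenclature checks in tests and examples.
loop_
_chem_comp.id
_chem_comp.name
_chem_comp.formula
_chem_comp.type
ATP "adenosine-5'-triphosphate" 'C10 H16 N5 O13 P3' non-polymer
ADP "adenosine-5'-diphosphate" 'C10 H15 N5 O10 P2' non-polymer
AMP 'adenosine monophosphate' 'C10 H14 N5 O7 P' non-polymer
GTP "guanosine-5'-triphosphate" 'C10 H16 N5 O14 P3' non-polymer
GDP "guanosine-5'-diphosphate" 'C10 H15 N5 O11 P2' non-polymer
NAD 'nicotinamide-adenine-dinucleotide' 'C21 H27 N7 O14 P2' non-polymer
FAD 'flavin adenine dinucleotide' 'C27 H33 N9 O15 P2' non-polymer
HEM 'protoporphyrin ix containing fe' 'C34 H32 Fe N4 O4' non-polymer
ZN 'zinc ion' Zn non-polymer
MG 'magnesium ion' Mg non-polymer
CA 'calcium ion' Ca non-polymer
NA 'sodium ion' Na non-polymer
K 'potassium ion' K non-polymer
CL 'chloride ion' Cl non-polymer
FE 'fe (iii) ion' Fe non-polymer
MN 'manganese (ii) ion' Mn non-polymer
SO4 'sulfate ion' 'O4 S' non-polymer
PO4 'phosphate ion' 'O4 P' non-polymer
GOL glycerol 'C3 H8 O3' non-polymer
EDO 1,2-ethanediol 'C2 H6 O2' non-polymer
NAG 2-acetamido-2-deoxy-beta-d-glucopyranose 'C8 H15 N O6' saccharide
HOH water 'H2 O' water
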