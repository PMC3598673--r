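name,dclass
Number of double bonds,constitutional
Number of aromatic bonds,constitutional
Number of Oxygen atoms,constitutional
Average distance sum connectivity index,constitutional
ESP-RNCS: Relative negative charged SA (SAMNEG*RNCG),constitutional
ESP-RPCS Relative positive charge SA (QMPOS/QTPLUS) [Zefirov's PC],constitutional
WPSA3 weighted PPSA (PPSA3*TMSA/1000) [Zefirov's PC],constitutional
ESP-FPSA-1 Fractional PPSA (PPSA-1/TMSA),constitutional
Translational Entropy,thermodynamic
Total Entropy,thermodynamic
Total Enthalpy,thermodynamic
Max partial charge,electrostatic
Max partial charge for a hydrogen atom,electrostatic
Max partial charge for a carbon atom,electrostatic
Max atomic orbital electronic population,quantum_chemical
ESP-Max net atomic charge,quantum_chemical
Avg electroph. react. index for a O atom,quantum_chemical
Max 1-electron react. index for a C atom,quantum_chemical
Max SIGMA-PI bond order,quantum_chemical
ESP-Max net atomic charge 2,quantum_chemical
ESP-Max net atomic charge for a N atom,quantum_chemical
"min(#HA, #HD) [Quantum-Chemical PC]",quantum_chemical
Min e-n attraction for a C-C bond,quantum_chemical
Min e-n attraction for a C-H bond,quantum_chemical
HOMO-1 energy (Molecular orbital related),quantum_chemical
LUMO + 1 energy (Molecular orbital related),quantum_chemical
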