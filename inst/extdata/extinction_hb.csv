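wavelength_nm,eps_hbo,eps_hbr
740,44.6,111.6
750,51.8,140.5
760,58.6,154.9
770,65.0,131.2
780,71.0,110.8
800,81.6,76.2
810,86.4,71.7
820,91.6,69.3
830,97.4,69.3
840,102.2,69.2
850,105.8,69.1
860,109.2,69.6
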