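#ifndef BSTAR_PG_H
#define BSTAR_PG_H
double rpg1(double c);
#endif
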