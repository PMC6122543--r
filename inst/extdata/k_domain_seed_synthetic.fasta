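>seedK_01
ESLERQLDTSLKQIRSTRTQYMLDQLSDLQRKEELLLESNRALRRKLEESNQELSQQLQEAHKENMELYKKVYGTREEANA
>seedK_02
ESLERQLRTSLKQIRITRVQYMLDQLSDVQRKEELLEESNRALRRLLEESNQELSVQLQSAHVENMELYKKVLGTRMEANA
>seedK_03
ESLEEQLDTSLKQIRSTRTQYMLDQLSDKQRHEELLLESNRALRVKLEESNQELSQQLQEAHKEFMELYKKVYGTREEANA
>seedK_04
ESLERQLDTSLKQIRSTRTQYMLDQLSELQRKEELLLESNRPLRRKLEESNQELSQQLQEAHKENMEPYKKTYGTRFEANG
>seedK_05
ESLNRQLDTMLKQIRSTHTQYMLSQLSDLQRKESLSLESNRILRRKLEESNQELSAQLQEHHKENMELYKKVYGTRREAND
>seedK_06
ESLERQLDTSLKQIRSTRTQYMLDQLSDLQRKERLLLESSRALRRKLEESNQELGQQLQEAHKENMQLYKKVSGTRNEANA
>seedK_07
ESYERQLDTSRKQIRSTRTQYRLDQLSDLQRKEEMLLESNRALRRKLEESWQELSQQLQEAHCENMELYKKVYGTREEANA
>seedK_08
ESLERILDTLLKQIRSTRTQYMLDQLSDYQRKGELLLESNRALRRKLEESLQELSQQLQERHKENMRQYKWPYGTREEANV
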