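>seedM_01
MGRGRVELKRIENKINRQVTFAKRRNGLLKKAYELSVLCDAEVALIIFSNRGKLYEFASS
>seedM_02
MGRGRVELKRIENKINRQVLFAKRRNGLLIKAYELSVLCDAEVALIIFSNRGKLNEFKSM
>seedM_03
MSRGRVMLKRPENKIHRQVTFAKRRNGLTKKAYELSVLCDVIVALIIFSNRGKPYEFASS
>seedM_04
MGRGRVELKRIENKINFQVTDAERRNGLLKKAYEHSVLCDAEVALIIFGNRGKLYEFAGS
>seedM_05
MGRGIVELKRIENKINRQAEFAKRRNGLLCDAYKLSVEIDNEVNLIIFWNRGKLYEFASS
>seedM_06
MGRGRVELKRIENKINRQVTHATRRNGLLKKDYELSVLCDTEVALIIFSNAGKLYEFASS
>seedM_07
MGRGWVESTRIENKINRQVTFAKQRNGLLKKAYEWSVLCDAEVALIIFHNRGKYYEFASS
>seedM_08
MGRGRDELKRIENKIKRQVTFAKRRNGLLKKATELCVLEDAEVANIIFSNRGKTYEFASS
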