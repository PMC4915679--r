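>BR synthetic exemplar, bacteriorhodopsin family
KMDFATYVQPHAESAFWVLNVDHILNIGGPNDVPYRLTVDVAGVYSRFVGYGLITYVTIK
RVKALAAKRGYRYAAWEAVIWFNATDEAVEGLGGAVSTTSLPNPVEKVLHALYLFCWLFM
VIAEEQFLLGESPEPYILHGSETAPGINAVYTGDTLGVATTAVSRGTGLKWPWYYFHWRT
AETFMDGQDEQGACKESPYTDAAKYYLALFPLSMRKEESPFRNIHDEYVQ
>BR2 synthetic exemplar, bacteriorhodopsin-2 family
RMDAATQFQPADESAFWDLNVQHNLLRGSPTDSRYRATGRVAVTASVLVQYAYVYSATVV
RSKRLAAKRYYRYAFWKAVIWLNAIDEAYGGGSKYVSTTYLPNLALWVGHALYLFCWVKM
TILEEQFLFGLSPVSYSLYGGYTAPVINAVYTQDLNKEASTLTSRGARLDWYAYAFHWFT
AATVAGEVDQVGWKKIDPYVYAYEYYNVRFPKSIRKEESAIKNIGRELVI
>HR synthetic exemplar, halorhodopsin family
RADFATLVKPAFEYAFWRLLVAVMDRIRGPIDVDYRLATMVDSTESIFVQYEYITDALVK
MRTALAAKRYGRYAFWPAFIWAHATMETVEGGSSYVSQTQVFNPAELVVHALSLKLWLKE
TIAGEQFLKCSSPERYSLVGILEGPDIQKVYTQMFDKEATTAWYCQAGLTWYWYYGHWTE
IRTFSDEMDEFQTSALSLYVANAVNYFGLFPLSVYKFESHIRAIGDELVQ
>SRI synthetic exemplar, sensory rhodopsin I family
RMDDAFQVQPAAEVAVTALSVQHMLIIDIPTNVDYRHTEDEDVAASIFLSYLYNTSATIL
LVKVLHAKWYYRYAFWLALTWANATDEEVVGVSLYVSMGSLPIPAIGVVAALTLFVWLKM
VIAEEQFLMGSAPAPYSLFGKYTGPGINAVYNQDTLKVATTAVSRDDCLTWYWYYFHWVK
AETVMDEADEQGAKPLTPYVAAAEYYSGLAQTSGRKAVSLTRNVGDDLVQ
>SRII synthetic exemplar, sensory rhodopsin II family (numbering reference)
RMDFATQVQPAAESAFWDLNVQHMLRIGSPTDVDYRLTTDVAVTASIFVQYAYITSATVK
RVKALAAKRYYRYAFWLAVIWANATDEAVEGGSKYVSTTSLPNPAEEVVHALYLFCWLKM
VIAEEQFLLGSSPEPYSLVGKYTAPGINAVYTQDTLKEATTAVSRGAGLTWYWYYFHWRT
AETFMDEADEQGWKKLSPYVAAAEYYNGLFPLSLRKFESLIRNIGDELVQ
>SR3 synthetic exemplar, sensory rhodopsin 3 family
RMLFARQVAPRASPAFWTFNVQHMLRIGSPLGVDYRFTTDLALTERNFVQYATVTSATPV
RVKHLAAKRLYRYKFWLAVIWAIAQDEAVSNVSVVVMTLSLPCPASEVVYALALKGTAKM
VIAEWQFLLGSSPSPYEAVGKYTAPVINAVYTSDWLKEAVTAVSRGAGLSWYWYYTHWRT
AEEFMDEPDEQGWKKLYVYVVAAEDAGGLQPVSLTKFESLIRNILDELVQ
>MR synthetic exemplar, middle rhodopsin family
RDDFSTVVQPAFSSIFWDLNVQTMFRIGSPTWVDYRSETDVAVLASIFYQYAYNTSATPK
RYKLLAKHAYYRLAFWLPVIVANAVDDAVIGGRKMDDDLLLRNPAEEVVKRLYEFLWLKM
VIAEEQFCLGSVPRGVSLVGVYTVPGSNAVYTQWTSKEATTAVSDGAGLGWYWYYFHWLT
AETFYIEADAGGWKKLVPYVAAGEYYNGLFELSTRKWEGLIRNIWDELVQ
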