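from,to
athol,royalston
royalston,winchendon
winchendon,gardner
barre,oakham
oakham,rutland
rutland,holden
holden,w_boylston
rutland,spencer
spencer,e_brookfield
e_brookfield,n_brookfield
n_brookfield,barre
paxton,leicester
leicester,charlton
charlton,oxford
charlton,sturbridge
auburn,millbury
millbury,sutton
sutton,douglas
northbridge,uxbridge
uxbridge,millville
millville,blackstone
uxbridge,mendon
dudley,webster
dudley,southbridge
milford,hopedale
hopedale,upton
milford,upton
grafton,westborough
westborough,southborough
worcester_s9,worcester_s10
worcester_s10,worcester_s11
worcester_s11,worcester_s12
worcester_s12,worcester_s13
worcester_s9,worcester_s13
worcester_s10,worcester_s12
northborough,shrewsbury
lancaster,lunenburg
lancaster,harvard
lancaster,clinton
clinton,boylston
lancaster,bolton
bolton,berlin
harvard,bolton
berlin,boylston
petersham,phillipston
phillipston,templeton
templeton,hubbardston
hubbardston,princeton
princeton,sterling
princeton,westminster
westminster,ashburnham
petersham,hardwick
hardwick,new_braintree
new_braintree,w_brookfield
w_brookfield,brookfield
w_brookfield,warren
athol,petersham
athol,phillipston
gardner,templeton
gardner,hubbardston
gardner,westminster
winchendon,ashburnham
winchendon,templeton
fitchburg,ashburnham
fitchburg,westminster
fitchburg,lunenburg
fitchburg,leominster
leominster,westminster
leominster,princeton
leominster,sterling
leominster,lancaster
leominster,lunenburg
sterling,lancaster
sterling,w_boylston
boylston,w_boylston
boylston,shrewsbury
berlin,northborough
hubbardston,barre
barre,hardwick
barre,new_braintree
oakham,new_braintree
n_brookfield,w_brookfield
brookfield,e_brookfield
brookfield,n_brookfield
warren,brookfield
sturbridge,brookfield
rutland,princeton
rutland,hubbardston
holden,princeton
spencer,leicester
spencer,charlton
paxton,rutland
charlton,dudley
oxford,webster
oxford,dudley
oxford,sutton
oxford,auburn
sturbridge,southbridge
charlton,southbridge
auburn,leicester
douglas,webster
douglas,uxbridge
sutton,northbridge
northbridge,grafton
grafton,sutton
grafton,millbury
mendon,milford
mendon,hopedale
mendon,blackstone
upton,northbridge
upton,grafton
upton,westborough
northborough,westborough
shrewsbury,grafton
worcester_s9,holden
worcester_s9,w_boylston
worcester_s10,paxton
worcester_s10,leicester
worcester_s11,shrewsbury
worcester_s11,w_boylston
worcester_s12,grafton
worcester_s12,millbury
worcester_s13,auburn
worcester_s13,leicester
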